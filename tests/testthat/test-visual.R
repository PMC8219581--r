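# Brute-force reference for the grating equation: scalar double loop.
reference_grating <- function(xs, ys, mean, contrast, sf, ori, phase,
                              env_sigma = NULL, mod_sigma = NULL) {
  out <- matrix(0, length(ys), length(xs))
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    x <- xs[j]; y <- ys[i]
    c_eff <- contrast
    if (!is.null(env_sigma))
      c_eff <- c_eff * exp(-(x^2 + y^2) / (2 * env_sigma^2))
    if (!is.null(mod_sigma))
      c_eff <- c_eff * exp(-(x^2 + y^2) / (2 * mod_sigma^2))
    out[i, j] <- mean * (1 + c_eff *
      cos(2 * pi * sf * (x * cos(ori) + y * sin(ori)) + phase))
  }
  out
}

test_that("grating luminance follows the carrier-times-envelope equation", {
  g <- patch_grid(11, 11)
  # zero contrast: flat field at the mean
  expect_true(all(grating_luminance(g$x, g$y, mean = 0.4, contrast = 0) == 0.4))
  # patch center, phase 0, unit-peak envelope: mean * (1 + contrast)
  expect_equal(grating_luminance(0, 0, mean = 0.5, contrast = 0.3, sf = 0.1,
                                 phase = 0, envelope_sigma = 5),
               0.5 * 1.3)
  expect_error(grating_luminance(0, 0, contrast = 1.5), "\\[0, 1\\]")
})

test_that("vectorized grating agrees with a double-loop reference to 1e-12", {
  xs <- (1:64) - 32.5
  ys <- 32.5 - (1:64)
  X <- matrix(rep(xs, each = 64), 64, 64)
  Y <- matrix(rep(ys, times = 64), 64, 64)
  for (case in list(
    list(ori = 0, phase = 0, env = NULL, mod = NULL),
    list(ori = pi / 7, phase = 1.1, env = 12, mod = NULL),
    list(ori = 2.4, phase = -0.4, env = 12, mod = 20))) {
    fast <- grating_luminance(X, Y, 0.5, 0.4, 0.07, case$ori, case$phase,
                              case$env, case$mod)
    slow <- reference_grating(xs, ys, 0.5, 0.4, 0.07, case$ori, case$phase,
                              case$env, case$mod)
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
})

test_that("Michelson contrast of an un-enveloped grating equals the parameter", {
  # one full 100-px period sampled at integer pixels: the extrema land
  # exactly on samples, so (max-min)/(max+min) is exact
  x <- 0:99
  L <- grating_luminance(x, 0, mean = 0.5, contrast = 0.3, sf = 1 / 100)
  mich <- (max(L) - min(L)) / (max(L) + min(L))
  expect_equal(mich, 0.3, tolerance = 1e-6)
  # energy: mean luminance over the full period equals the mean parameter
  expect_equal(mean(L), 0.5, tolerance = 1e-3)
})

test_that("rectangular checkerboard parity alternates and is periodic", {
  expect_identical(checkerboard_value(0.1, 0.1, "rect", 10, 10), 0)
  expect_identical(checkerboard_value(10.1, 0.1, "rect", 10, 10), 1)
  g <- patch_grid(50, 50)
  p0 <- checkerboard_value(g$x, g$y, "rect", 7, 9)
  p_shift <- checkerboard_value(g$x + 14, g$y, "rect", 7, 9)
  expect_identical(p0, p_shift)
  expect_error(checkerboard_value(0, 0, "rect", -1, 10), "positive")
})

test_that("radial checkerboard flips parity under a one-sector rotation", {
  n_sectors <- 8
  rot <- 2 * pi / n_sectors
  g <- patch_grid(100, 100)
  x <- g$x; y <- g$y
  p0 <- checkerboard_value(x, y, "radial", n_sectors = n_sectors,
                           ring_width = 10)
  xr <- x * cos(rot) - y * sin(rot)
  yr <- x * sin(rot) + y * cos(rot)
  p1 <- checkerboard_value(xr, yr, "radial", n_sectors = n_sectors,
                           ring_width = 10)
  # brute force over the grid, skipping points numerically on a sector or
  # ring boundary where the parity is not defined
  ang <- atan2(y, x) %% (2 * pi)
  r <- sqrt(x^2 + y^2)
  off_boundary <- r > 1e-9 &
    abs(ang / (2 * pi / n_sectors) - round(ang / (2 * pi / n_sectors))) > 1e-6 &
    abs(r / 10 - round(r / 10)) > 1e-6
  expect_true(all((p1 == 1 - p0)[off_boundary]))
})

test_that("shape masks carve rectangle, ellipse and cross apertures", {
  patch <- raster_patch(array(0.5, c(21, 21, 3)))
  rect <- apply_shape_mask(patch, "rectangle")
  expect_true(all(rect$alpha == 1))
  ell <- apply_shape_mask(patch, "ellipse")
  expect_identical(ell$alpha[11, 11], 1)
  expect_identical(ell$alpha[1, 1], 0)
  expect_identical(ell$alpha[1, 21], 0)
  expect_identical(ell$alpha[21, 1], 0)
  expect_identical(ell$alpha[21, 21], 0)
  cross <- apply_shape_mask(patch, "cross")
  expect_identical(cross$alpha[11, 11], 1)
  expect_identical(cross$alpha[1, 1], 0)
  expect_error(apply_shape_mask(patch, "hexagon"), "unknown shape")
})

test_that("the noise filter adds bounded zero-mean uniform noise", {
  patch <- raster_patch(array(0.5, c(1000, 1000, 3)))
  expect_identical(apply_noise_filter(patch, 0), patch)
  noisy <- apply_noise_filter(patch, 0.1, seed = 11)
  delta <- noisy$pixels[, , 1] - 0.5
  # CLT bound: |mean| < 3 * (a/sqrt(3)) / sqrt(n) for n = 1e6, a = 0.1
  expect_lt(abs(mean(delta)), 3 * (0.1 / sqrt(3)) / 1000)
  expect_true(all(noisy$pixels >= 0 & noisy$pixels <= 1))
  expect_true(all(abs(delta) <= 0.1 + 1e-12))
  # reproducible under the same seed
  expect_identical(apply_noise_filter(patch, 0.1, seed = 11), noisy)
})

test_that("noise-bit quantization rounds stochastically between levels", {
  # values exactly on a level never move
  v <- c(0, 1, 10 / 255, 200 / 255)
  expect_identical(quantize_noise_bit(v, seed = 1), c(0, 255, 10, 200))
  # outputs are always one of the two adjacent levels
  x <- rep(0.4242, 1000)
  q <- quantize_noise_bit(x, seed = 2)
  expect_true(all(q %in% c(floor(0.4242 * 255), ceiling(0.4242 * 255))))
  # midpoint value: binomial(0.5) mean over 40000 draws
  m <- mean(quantize_noise_bit(rep(0.5 / 255, 40000), seed = 3))
  expect_lt(abs(m - 0.5), 3 * 0.5 / 200)
  expect_error(quantize_noise_bit(1.5), "\\[0, 1\\]")
})

test_that("stimulus rendering dispatches per type and is deterministic", {
  d <- unit_display()
  ctx <- list(frame = 0L, total_frames = 6L, refresh_rate = 60)
  red <- stimulus_spec("p", "patch", "rectangle", list(
    size_x = property_constant(10, "px"), size_y = property_constant(10, "px"),
    color = property_constant(c(1, 0, 0))))
  patch <- render_stimulus_frame(red, ctx = ctx, display = d)
  expect_identical(dim(patch$pixels), c(10L, 10L, 3L))
  expect_true(all(patch$pixels[, , 1] == 1))
  expect_true(all(patch$pixels[, , 2] == 0))
  expect_true(all(patch$alpha == 1))

  vert <- stimulus_spec("g", "grating", "rectangle", list(
    size_x = property_constant(16, "px"), size_y = property_constant(16, "px"),
    spatial_frequency = property_constant(0.1, "px"),
    mean_luminance = property_constant(0.5),
    contrast = property_constant(0.8),
    gratingRotation = property_constant(0, "rad")))
  gp <- render_stimulus_frame(vert, ctx = ctx, display = d)
  # orientation 0: columns vary, rows constant
  expect_true(all(apply(gp$pixels[, , 1], 2, function(col) diff(range(col))) == 0))
  expect_gt(diff(range(gp$pixels[1, , 1])), 0.5)

  noisy <- stimulus_spec("n", "patch", "rectangle", list(
    size_x = property_constant(12, "px"), size_y = property_constant(12, "px"),
    noise_filter = property_constant(0.2)))
  a <- render_stimulus_frame(noisy, ctx = ctx, display = d, seed = 5)
  b <- render_stimulus_frame(noisy, ctx = ctx, display = d, seed = 5)
  expect_identical(a, b)
  c2 <- render_stimulus_frame(noisy, ctx = ctx, display = d, seed = 6)
  expect_false(identical(a, c2))

  tone <- stimulus_spec("t", "tone", properties = list(
    tone_frequency = property_constant(440)))
  expect_error(render_stimulus_frame(tone, ctx = ctx, display = d),
               "auditory")
})

test_that("text stimuli rasterize through the built-in bitmap font", {
  d <- unit_display()
  txt <- stimulus_spec("t", "text", "rectangle", list(
    size_x = property_constant(80, "px"), size_y = property_constant(30, "px"),
    text_string = property_constant("OK"),
    color = property_constant(c(1, 1, 1))))
  p <- render_stimulus_frame(txt, display = d)
  expect_true(any(p$alpha > 0))
  expect_true(any(p$alpha == 0))
})

test_that("scene compositing is alpha-over with screen clipping", {
  d <- display_profile(40, 30, 10)
  bg <- c(0.2, 0.2, 0.2)
  empty <- composite_scene_frame(list(), d, bg)
  expect_true(all(empty$pixels == 0.2))
  expect_identical(dim(empty$pixels), c(30L, 40L, 3L))

  opaque <- raster_patch(array(1, c(5, 5, 3)), origin = c(3L, 4L))
  one <- composite_scene_frame(list(opaque), d, bg)
  expect_true(all(one$pixels[3:7, 4:8, ] == 1))
  one$pixels[3:7, 4:8, ] <- 0.2
  expect_true(all(one$pixels == 0.2))

  p1 <- raster_patch(array(1, c(4, 4, 3)), origin = c(1L, 1L))
  p2 <- raster_patch(array(0, c(4, 4, 3)), origin = c(20L, 30L))
  expect_identical(composite_scene_frame(list(p1, p2), d, bg),
                   composite_scene_frame(list(p2, p1), d, bg))

  # partially off-screen patches clip without error
  off <- raster_patch(array(1, c(10, 10, 3)), origin = c(-4L, 36L))
  clipped <- composite_scene_frame(list(off), d, bg)
  expect_true(all(clipped$pixels[1:5, 36:40, ] == 1))
})

test_that("frames round-trip through 8-bit PNG", {
  d <- display_profile(16, 12, 10)
  buf <- composite_scene_frame(list(), d, c(0.25, 0.5, 0.75))
  path <- tempfile(fileext = ".png")
  write_frame_png(buf, path)
  back <- png::readPNG(path)
  expect_identical(dim(back), c(12L, 16L, 3L))
  expect_true(max(abs(back - buf$pixels)) <= 1 / 255)
  unlink(path)
})
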