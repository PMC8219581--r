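#' Raster patches
#'
#' The unit of visual compositing: a small RGB raster plus an alpha mask,
#' positioned on the screen. Pixel values are linear luminance fractions in
#' \[0, 1\] per channel.
#'
#' @param pixels h x w x 3 numeric array in \[0, 1\].
#' @param alpha h x w matrix in \[0, 1\] (default fully opaque).
#' @param origin Integer `c(row, col)` of the patch's top-left pixel in
#'   screen raster coordinates (1-based; may fall outside the screen, the
#'   compositor clips).
#' @return A `raster_patch` object.
#' @export
raster_patch <- function(pixels, alpha = NULL, origin = c(1L, 1L)) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("`pixels` must be an h x w x 3 array", call. = FALSE)
  if (is.null(alpha)) alpha <- matrix(1, d[1], d[2])
  if (!all(dim(alpha) == d[1:2]))
    stop("`alpha` must match the pixel raster h x w", call. = FALSE)
  structure(list(pixels = pixels, alpha = alpha,
                 origin = as.integer(origin)),
            class = "raster_patch")
}

# Centered pixel-center coordinate grids for a w x h patch:
# +x right, +y up, origin at the patch center.
patch_grid <- function(w, h) {
  xs <- (1:w) - (w + 1) / 2
  ys <- (h + 1) / 2 - (1:h)
  list(x = matrix(rep(xs, each = h), h, w),
       y = matrix(rep(ys, times = w), h, w))
}

# Run expr with a reproducible, locally scoped RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Luminance of a (possibly Gabor) grating at given coordinates
#'
#' Sinusoidal luminance grating
#' `L = mean * (1 + c_eff(x, y) * cos(2*pi*sf*(x*cos(theta) + y*sin(theta)) + phase))`
#' where the effective contrast `c_eff = contrast * G_env * G_mod`.
#' `G_env` is a unit-peak isotropic Gaussian of width `envelope_sigma`
#' centered on the patch (a Gabor) or 1 when absent; `G_mod` is a second
#' unit-peak Gaussian of width `carrier_mod_sigma` implementing
#' carrier-contrast modulation, or 1 when absent. With `orientation = 0`
#' the carrier varies along x (a vertical grating).
#'
#' @param x,y Coordinates in px (vectors or matrices, patch-centered).
#' @param mean Mean luminance fraction.
#' @param contrast Michelson contrast in \[0, 1\].
#' @param sf Spatial frequency in cycles/px.
#' @param orientation Carrier orientation in radians (counterclockwise).
#' @param phase Carrier phase in radians.
#' @param envelope_sigma Gaussian envelope sigma in px, or `NULL`.
#' @param carrier_mod_sigma Contrast-modulation sigma in px, or `NULL`.
#' @return Luminance fraction(s), same shape as `x`.
#' @export
grating_luminance <- function(x, y, mean = 0.5, contrast = 1, sf = 0.05,
                              orientation = 0, phase = 0,
                              envelope_sigma = NULL,
                              carrier_mod_sigma = NULL) {
  if (any(contrast < 0) || any(contrast > 1))
    stop("`contrast` must be within [0, 1]", call. = FALSE)
  c_eff <- contrast
  if (!is.null(envelope_sigma))
    c_eff <- c_eff * exp(-(x^2 + y^2) / (2 * envelope_sigma^2))
  if (!is.null(carrier_mod_sigma))
    c_eff <- c_eff * exp(-(x^2 + y^2) / (2 * carrier_mod_sigma^2))
  u <- x * cos(orientation) + y * sin(orientation)
  mean * (1 + c_eff * cos(2 * pi * sf * u + phase))
}

#' Checkerboard parity at given coordinates
#'
#' Rectangular: `(floor(x/check_w) + floor(y/check_h)) mod 2`.
#' Radial: `(sector_index(atan2(y, x)) + floor(r/ring_width)) mod 2` with
#' `n_sectors` equal angular sectors. Parity 0/1 selects one of the two
#' check colors.
#'
#' @param x,y Coordinates in px (centered).
#' @param kind `"rect"` or `"radial"`.
#' @param check_w,check_h Rectangular check sizes in px.
#' @param n_sectors Number of angular sectors (radial).
#' @param ring_width Ring width in px (radial).
#' @return Parity values in \{0, 1\}, same shape as `x`.
#' @export
checkerboard_value <- function(x, y, kind = c("rect", "radial"),
                               check_w = 10, check_h = 10,
                               n_sectors = 8, ring_width = 10) {
  kind <- match.arg(kind)
  if (kind == "rect") {
    if (check_w <= 0 || check_h <= 0)
      stop("check sizes must be positive", call. = FALSE)
    (floor(x / check_w) + floor(y / check_h)) %% 2
  } else {
    if (n_sectors < 1 || ring_width <= 0)
      stop("need n_sectors >= 1 and ring_width > 0", call. = FALSE)
    ang <- atan2(y, x) %% (2 * pi)
    sector <- floor(ang / (2 * pi / n_sectors))
    r <- sqrt(x^2 + y^2)
    (sector + floor(r / ring_width)) %% 2
  }
}

#' Apply an aperture shape mask to a patch
#'
#' Sets alpha to 1 inside the shape and 0 outside. The ellipse is
#' inscribed in the patch (`(2x/w)^2 + (2y/h)^2 <= 1`); the cross is the
#' union of a horizontal and a vertical bar of thickness
#' `arm_fraction * min(w, h)`.
#'
#' @param patch A [raster_patch()].
#' @param shape `"rectangle"`, `"ellipse"` or `"cross"`.
#' @param arm_fraction Bar thickness of the cross as a fraction of the
#'   smaller patch dimension.
#' @return The patch with its alpha replaced by the shape mask.
#' @export
apply_shape_mask <- function(patch, shape, arm_fraction = 0.2) {
  h <- dim(patch$pixels)[1]; w <- dim(patch$pixels)[2]
  g <- patch_grid(w, h)
  mask <- switch(shape,
    rectangle = matrix(1, h, w),
    ellipse = ((2 * g$x / w)^2 + (2 * g$y / h)^2 <= 1) * 1,
    cross = {
      t2 <- arm_fraction * min(w, h) / 2
      ((abs(g$y) <= t2 & abs(g$x) <= w / 2) |
       (abs(g$x) <= t2 & abs(g$y) <= h / 2)) * 1
    },
    stop(sprintf("unknown shape '%s'", shape), call. = FALSE))
  patch$alpha <- patch$alpha * mask
  patch
}

#' Add pixel noise to a patch
#'
#' Adds zero-mean uniform noise of half-range `noise_amplitude` to every
#' pixel (the same draw across the three channels, i.e. luminance noise),
#' then clips to \[0, 1\].
#'
#' @param patch A [raster_patch()].
#' @param noise_amplitude Half-range of the uniform noise, in \[0, 1\].
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return The noisy patch.
#' @export
apply_noise_filter <- function(patch, noise_amplitude, seed = NULL) {
  if (noise_amplitude < 0 || noise_amplitude > 1)
    stop("`noise_amplitude` must be within [0, 1]", call. = FALSE)
  if (noise_amplitude == 0) return(patch)
  h <- dim(patch$pixels)[1]; w <- dim(patch$pixels)[2]
  noise <- with_local_seed(seed,
    matrix(stats::runif(h * w, -noise_amplitude, noise_amplitude), h, w))
  for (ch in 1:3)
    patch$pixels[, , ch] <- pmin(1, pmax(0, patch$pixels[, , ch] + noise))
  patch
}

#' Noise-bit stochastic quantization
#'
#' Quantizes real values in \[0, 1\] to the `2^bit_depth` uniform levels of
#' the display by stochastic rounding: a value between two adjacent levels
#' goes to the upper level with probability equal to its fractional
#' position between them, independently per pixel and per frame. The
#' expected displayed value therefore equals the target value exactly,
#' which makes contrast effectively quasi-continuous on a discrete panel.
#'
#' @param values Numeric vector/matrix/array in \[0, 1\].
#' @param bit_depth Display bit depth (default 8).
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return Integer levels in `0:(2^bit_depth - 1)`, same shape as `values`.
#' @export
quantize_noise_bit <- function(values, bit_depth = 8, seed = NULL) {
  if (any(values < 0) || any(values > 1))
    stop("`values` must be within [0, 1]", call. = FALSE)
  n_levels <- 2^bit_depth
  scaled <- values * (n_levels - 1)
  lower <- floor(scaled)
  frac <- scaled - lower
  up <- with_local_seed(seed,
    stats::runif(length(values)) < frac)
  out <- lower + as.numeric(up)
  out[out > n_levels - 1] <- n_levels - 1
  dim(out) <- dim(values)
  out
}
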