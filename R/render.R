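#' Frame buffers and scene compositing
#'
#' Screen coordinates put the origin at the screen center with +x right
#' and +y up; angles are radians counterclockwise from +x. Stimulus
#' positions are center coordinates. The frame buffer raster is stored
#' row-major with row 1 at the top of the screen.
#'
#' @name rendering
NULL

# Deterministic per-frame seed stream below 2^31.
derive_seed <- function(base, ...) {
  m <- 2147483647
  s <- as.numeric(base) %% m
  for (k in c(...)) s <- (s * 69069 + as.numeric(k) * 1013 + 7) %% m
  as.integer(s)
}

new_frame_buffer <- function(display, background = c(0.5, 0.5, 0.5)) {
  h <- display$height_px; w <- display$width_px
  structure(list(height = h, width = w,
                 pixels = array(rep(background, each = h * w), c(h, w, 3))),
            class = "frame_buffer")
}

#' Render one frame of one stimulus
#'
#' Resolves the stimulus properties for the given trial bindings and frame
#' context (converting spatial units to pixels through the display
#' profile), dispatches on the stimulus type, applies the aperture shape
#' mask and the optional pixel-noise filter, and returns a positioned
#' [raster_patch()]. Rendering is a pure function of the specification,
#' the resolved properties, the frame index and the seed.
#'
#' @param stim A visual [stimulus_spec()].
#' @param bindings Named list of this trial's variable values.
#' @param ctx Frame context: `frame` (0-based), `total_frames`,
#'   `refresh_rate`, and optionally `dot_state` carried between frames.
#' @param display A [display_profile()].
#' @param seed Integer seed for the stochastic elements (noise filter,
#'   dot updates); derive it per frame for animated noise.
#' @return A [raster_patch()]; for dot stimuli the updated dot-field state
#'   is attached as attribute `"dot_state"`.
#' @export
render_stimulus_frame <- function(stim, bindings = list(),
                                  ctx = list(frame = 0L, total_frames = 1L,
                                             refresh_rate = 60),
                                  display, seed = 0L) {
  if (stim$type %in% auditory_types)
    stop(sprintf("stimulus '%s' is auditory; use the audio synthesizers",
                 stim$name), call. = FALSE)
  rp <- function(prop, default = NULL)
    resolve_px(stim, prop, bindings, ctx, display, default)

  w <- max(1L, as.integer(round(rp("size_x", 100))))
  h <- max(1L, as.integer(round(rp("size_y", 100))))
  pos_x <- rp("position_x", 0)
  pos_y <- rp("position_y", 0)
  ori <- (rp("orientation", 0) %||% 0) +
    (if (!is.null(stim$properties$gratingRotation)) rp("gratingRotation", 0) else 0)
  color <- rp("color", c(1, 1, 1)); if (length(color) == 1L) color <- rep(color, 3)
  contrast <- rp("contrast", 1)
  g <- patch_grid(w, h)
  # rotated sampling frame for patterns defined along an axis
  xr <- g$x * cos(ori) + g$y * sin(ori)
  yr <- -g$x * sin(ori) + g$y * cos(ori)

  dot_state <- NULL
  px <- switch(stim$type,
    patch = {
      col_eff <- 0.5 + contrast * (color - 0.5)
      array(rep(col_eff, each = h * w), c(h, w, 3))
    },
    gradient = {
      color2 <- rp("color2", c(0, 0, 0)); if (length(color2) == 1L) color2 <- rep(color2, 3)
      t <- (xr - min(xr)) / max(max(xr) - min(xr), 1e-12)
      arr <- array(0, c(h, w, 3))
      for (ch in 1:3) arr[, , ch] <- color[ch] + t * (color2[ch] - color[ch])
      arr
    },
    grating = {
      lum <- grating_luminance(
        g$x, g$y,
        mean = rp("mean_luminance", 0.5),
        contrast = contrast,
        sf = rp("spatial_frequency", 0.05),
        orientation = ori,
        phase = rp("phase", 0),
        envelope_sigma = rp("envelope_sigma"),
        carrier_mod_sigma = rp("carrier_contrast_mod_sigma"))
      arr <- array(0, c(h, w, 3))
      for (ch in 1:3) arr[, , ch] <- lum * color[ch]
      arr
    },
    checkerboard_rect = ,
    checkerboard_radial = {
      color2 <- rp("color2", c(0, 0, 0)); if (length(color2) == 1L) color2 <- rep(color2, 3)
      parity <- if (stim$type == "checkerboard_rect")
        checkerboard_value(xr, yr, "rect",
                           check_w = rp("check_w", 10),
                           check_h = rp("check_h", 10))
      else
        checkerboard_value(xr, yr, "radial",
                           n_sectors = rp("n_sectors", 8),
                           ring_width = rp("ring_width", 10))
      arr <- array(0, c(h, w, 3))
      for (ch in 1:3) arr[, , ch] <- color[ch] * (1 - parity) + color2[ch] * parity
      arr
    },
    dots_linear = ,
    dots_radial = ,
    dots_expansive = {
      kind <- sub("^dots_", "", stim$type)
      aperture <- min(w, h) / 2
      state <- ctx$dot_state
      if (is.null(state))
        state <- dot_field_init(n_dots = rp("n_dots", 100),
                                aperture_radius = aperture,
                                coherence = rp("coherence", 1),
                                lifetime = rp("dot_lifetime", 60),
                                seed = derive_seed(seed, 11))
      else
        state <- update_dot_field(state, kind,
                                  speed = rp("dot_speed", 1),
                                  direction = rp("dot_direction", 0),
                                  seed = derive_seed(seed, 13, ctx$frame))
      dot_state <- state
      ras <- rasterize_dots(state, w, h, rp("dot_radius", 2), color,
                            background = c(0, 0, 0))
      shape_alpha <- ras$alpha
      ras$pixels
    },
    text = {
      txt <- resolve_property(stim, "text_string", bindings, ctx)
      scale <- max(1L, as.integer(round(rp("text_scale", 3))))
      ras <- rasterize_text(as.character(txt), scale, color, w, h)
      shape_alpha <- ras$alpha
      ras$pixels
    },
    image = {
      path <- resolve_property(stim, "file_path", bindings, ctx)
      read_image_raster(path, w, h)
    },
    stop(sprintf("no renderer for stimulus type '%s'", stim$type), call. = FALSE))

  patch <- raster_patch(px)
  if (exists("shape_alpha", inherits = FALSE)) patch$alpha <- shape_alpha
  patch <- apply_shape_mask(patch, stim$shape)
  nf <- rp("noise_filter", 0)
  if (nf > 0)
    patch <- apply_noise_filter(patch, nf, seed = derive_seed(seed, 17, ctx$frame))

  # center position -> top-left raster index on screen
  col_c <- (display$width_px + 1) / 2 + pos_x
  row_c <- (display$height_px + 1) / 2 - pos_y
  patch$origin <- c(as.integer(round(row_c - (h - 1) / 2)),
                    as.integer(round(col_c - (w - 1) / 2)))
  if (!is.null(dot_state)) attr(patch, "dot_state") <- dot_state
  patch
}

#' Composite rendered patches into a full frame
#'
#' Alpha-over compositing in draw order onto a background-filled buffer;
#' patches are clipped at the screen edges.
#'
#' @param patches List of [raster_patch()] objects in draw order.
#' @param display A [display_profile()].
#' @param background Background RGB (luminance fractions).
#' @return A `frame_buffer` (fields `height`, `width`, `pixels`
#'   H x W x 3 in \[0, 1\]).
#' @export
composite_scene_frame <- function(patches, display,
                                  background = c(0.5, 0.5, 0.5)) {
  buf <- new_frame_buffer(display, background)
  for (p in patches) {
    ph <- dim(p$pixels)[1]; pw <- dim(p$pixels)[2]
    r0 <- p$origin[1]; c0 <- p$origin[2]
    rows <- max(1L, r0):min(buf$height, r0 + ph - 1L)
    cols <- max(1L, c0):min(buf$width, c0 + pw - 1L)
    if (length(rows) == 0L || length(cols) == 0L ||
        rows[1] > rows[length(rows)] || cols[1] > cols[length(cols)]) next
    pr <- rows - r0 + 1L; pc <- cols - c0 + 1L
    a <- p$alpha[pr, pc, drop = FALSE]
    for (ch in 1:3)
      buf$pixels[rows, cols, ch] <-
        p$pixels[pr, pc, ch] * a + buf$pixels[rows, cols, ch] * (1 - a)
  }
  buf$pixels[] <- pmin(1, pmax(0, buf$pixels))
  buf
}

#' Write a frame buffer (or patch) to an 8-bit PNG
#'
#' @param frame A `frame_buffer` or [raster_patch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  px <- frame$pixels
  png::writePNG(px, path)
  invisible(path)
}

# Read a PNG and nearest-neighbor resample to w x h RGB.
read_image_raster <- function(path, w, h) {
  if (!file.exists(path)) stop(sprintf("no such image file: %s", path),
                               call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  ih <- dim(img)[1]; iw <- dim(img)[2]
  ri <- pmin(ih, pmax(1L, as.integer(ceiling((1:h) * ih / h))))
  ci <- pmin(iw, pmax(1L, as.integer(ceiling((1:w) * iw / w))))
  img[ri, ci, , drop = FALSE]
}
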