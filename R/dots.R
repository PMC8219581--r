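#' Random-dot kinematograms
#'
#' A dot field is a set of dots inside a circular aperture. A coherence
#' fraction of dots are *signal* dots that move according to the motion
#' kind — linear translation, radial (rotation about the aperture center,
#' i.e. tangential motion) or expansive (optic-flow expansion along the
#' outward ray; negative speed contracts). The remaining *noise* dots move
#' with the same speed in an independently drawn uniform random direction
#' on every update. Membership is assigned at birth (Newsome-style): a dot
#' is signal or noise for its whole lifetime, and the expected signal
#' fraction equals the coherence. Dots that exceed their lifetime or leave
#' the aperture are redrawn uniformly inside the aperture with age 0.
#'
#' @name dot-field
NULL

#' Initialize a dot field
#'
#' @param n_dots Number of dots.
#' @param aperture_radius Aperture radius in px (> 0).
#' @param coherence Signal fraction in \[0, 1\].
#' @param lifetime Dot lifetime in frames (>= 1).
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return A `dot_field_state`: positions (n x 2, aperture-centered px),
#'   ages (frames), signal membership, and the parameters above.
#' @export
dot_field_init <- function(n_dots, aperture_radius, coherence = 1,
                           lifetime = 60, seed = NULL) {
  if (aperture_radius <= 0) stop("`aperture_radius` must be > 0", call. = FALSE)
  if (coherence < 0 || coherence > 1)
    stop("`coherence` must be within [0, 1]", call. = FALSE)
  with_local_seed(seed, {
    pos <- runif_disk(n_dots, aperture_radius)
    structure(list(
      positions = pos,
      ages = sample.int(max(1L, as.integer(lifetime)), n_dots,
                        replace = TRUE) - 1L,
      is_signal = stats::runif(n_dots) < coherence,
      n_dots = as.integer(n_dots),
      aperture_radius = aperture_radius,
      coherence = coherence,
      lifetime = as.integer(lifetime)),
      class = "dot_field_state")
  })
}

# n uniform points in a disk of given radius
runif_disk <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}

#' Advance a dot field by one frame
#'
#' @param state A `dot_field_state` from [dot_field_init()].
#' @param kind Motion kind: `"linear"`, `"radial"` or `"expansive"`.
#' @param speed Dot speed in px/frame (radial: arc length per frame;
#'   expansive: radial displacement per frame, negative contracts).
#' @param direction Signal direction in radians (linear motion only).
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return The updated `dot_field_state`.
#' @export
update_dot_field <- function(state, kind = c("linear", "radial", "expansive"),
                             speed = 1, direction = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (state$aperture_radius <= 0)
    stop("`aperture_radius` must be > 0", call. = FALSE)
  with_local_seed(seed, {
    n <- state$n_dots
    pos <- state$positions
    sig <- state$is_signal

    new_pos <- pos
    if (any(sig)) {
      p <- pos[sig, , drop = FALSE]
      moved <- switch(kind,
        linear = cbind(p[, 1] + speed * cos(direction),
                       p[, 2] + speed * sin(direction)),
        radial = {
          r <- sqrt(p[, 1]^2 + p[, 2]^2)
          dtheta <- ifelse(r > 1e-12, speed / r, 0)
          ang <- atan2(p[, 2], p[, 1]) + dtheta
          cbind(r * cos(ang), r * sin(ang))
        },
        expansive = {
          r <- sqrt(p[, 1]^2 + p[, 2]^2)
          keep <- r <= 1e-12
          rn <- pmax(0, r + speed)
          scale <- ifelse(keep, 1, rn / pmax(r, 1e-12))
          cbind(p[, 1] * scale, p[, 2] * scale)
        })
      new_pos[sig, ] <- moved
    }
    if (any(!sig)) {
      m <- sum(!sig)
      ang <- stats::runif(m, 0, 2 * pi)
      new_pos[!sig, ] <- pos[!sig, , drop = FALSE] +
        speed * cbind(cos(ang), sin(ang))
    }

    ages <- state$ages + 1L
    out <- sqrt(new_pos[, 1]^2 + new_pos[, 2]^2) > state$aperture_radius
    dead <- out | ages >= state$lifetime
    if (any(dead)) {
      k <- sum(dead)
      new_pos[dead, ] <- runif_disk(k, state$aperture_radius)
      ages[dead] <- 0L
      sig[dead] <- stats::runif(k) < state$coherence
    }
    state$positions <- new_pos
    state$ages <- ages
    state$is_signal <- sig
    state
  })
}

# Rasterize a dot field into a patch: filled circles of dot_radius px.
rasterize_dots <- function(state, w, h, dot_radius, color, background) {
  px <- array(rep(background, each = h * w), c(h, w, 3))
  alpha <- matrix(0, h, w)
  g <- patch_grid(w, h)
  for (i in seq_len(state$n_dots)) {
    dx <- g$x - state$positions[i, 1]
    dy <- g$y - state$positions[i, 2]
    hit <- dx^2 + dy^2 <= dot_radius^2
    if (any(hit)) {
      alpha[hit] <- 1
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[hit] <- color[ch]
        px[, , ch] <- plane
      }
    }
  }
  list(pixels = px, alpha = alpha)
}
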