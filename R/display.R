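#' Describe the physical and temporal properties of a display
#'
#' A display profile carries everything needed to convert between stimulus
#' units: the pixel grid, the pixel density, the refresh rate, the maximum
#' luminance of the panel and the viewing distance of the observer.
#'
#' @param width_px,height_px Screen resolution in pixels (positive integers).
#' @param pixels_per_cm Pixel density in px/cm.
#' @param refresh_rate Refresh rate in Hz.
#' @param max_luminance Maximum luminance of the panel in cd/m^2.
#' @param viewing_distance Viewing distance in cm.
#' @param model_name Free-text device label.
#' @return An object of class `display_profile`.
#' @examples
#' d <- display_profile(1024, 768, pixels_per_cm = 52, refresh_rate = 60,
#'                      max_luminance = 600, viewing_distance = 57.3)
#' deg_to_px(1, d)
#' @export
display_profile <- function(width_px, height_px, pixels_per_cm,
                            refresh_rate = 60, max_luminance = 500,
                            viewing_distance = 57.3,
                            model_name = "generic") {
  prof <- structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixels_per_cm = as.numeric(pixels_per_cm),
         refresh_rate = as.numeric(refresh_rate),
         max_luminance = as.numeric(max_luminance),
         viewing_distance = as.numeric(viewing_distance),
         model_name = as.character(model_name)),
    class = "display_profile")
  check_display(prof)
  prof
}

check_display <- function(display) {
  if (!inherits(display, "display_profile"))
    stop("`display` must be a display_profile object", call. = FALSE)
  num <- c("width_px", "height_px", "pixels_per_cm", "refresh_rate",
           "max_luminance", "viewing_distance")
  for (f in num) {
    v <- display[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("display_profile field '%s' must be a single positive finite number", f),
           call. = FALSE)
  }
  invisible(display)
}

#' @export
print.display_profile <- function(x, ...) {
  cat(sprintf("<display_profile> %s\n", x$model_name))
  cat(sprintf("  %d x %d px, %.4g px/cm, %g Hz\n",
              x$width_px, x$height_px, x$pixels_per_cm, x$refresh_rate))
  cat(sprintf("  max luminance %g cd/m^2, viewing distance %g cm\n",
              x$max_luminance, x$viewing_distance))
  invisible(x)
}

#' Read display profiles from a JSON table
#'
#' The package ships a small user-editable table of example devices in
#' `system.file("extdata", "display_profiles.json", package = "stimkit")`.
#' Nominal maximum-luminance values vary across panel series and with panel
#' age, so the table is meant to be edited, not trusted as a calibration.
#'
#' @param path Path to a JSON file: an array of objects with the
#'   `display_profile` field names.
#' @return A named list of `display_profile` objects, keyed by `model_name`.
#' @export
load_display_profiles <- function(path = system.file("extdata", "display_profiles.json",
                                                     package = "stimkit")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  profs <- lapply(raw, function(p)
    display_profile(p$width_px, p$height_px, p$pixels_per_cm, p$refresh_rate,
                    p$max_luminance, p$viewing_distance, p$model_name))
  names(profs) <- vapply(profs, function(p) p$model_name, character(1))
  profs
}

#' Convert degrees of visual angle to pixels
#'
#' Uses the exact chord formula `2 * d * tan(theta/2) * pixels_per_cm`
#' rather than the small-angle approximation, so the conversion remains
#' correct at large eccentricities; for angles below about 5 degrees the
#' two agree to well under 0.1%.
#'
#' @param angle Angle in degrees of visual angle (>= 0).
#' @param display A [display_profile()].
#' @return Length in pixels.
#' @export
deg_to_px <- function(angle, display) {
  check_display(display)
  if (any(!is.finite(angle))) stop("`angle` must be finite", call. = FALSE)
  if (any(angle < 0)) stop("`angle` must be non-negative", call. = FALSE)
  2 * display$viewing_distance * tan(angle * pi / 360) * display$pixels_per_cm
}

#' Convert pixels to degrees of visual angle
#'
#' Exact inverse of [deg_to_px()].
#'
#' @param length_px Length in pixels (>= 0).
#' @inheritParams deg_to_px
#' @return Angle in degrees of visual angle.
#' @export
px_to_deg <- function(length_px, display) {
  check_display(display)
  if (any(!is.finite(length_px))) stop("`length_px` must be finite", call. = FALSE)
  if (any(length_px < 0)) stop("`length_px` must be non-negative", call. = FALSE)
  2 * atan(length_px / (2 * display$viewing_distance * display$pixels_per_cm)) * 180 / pi
}

#' Convert a length in any supported unit to pixels
#'
#' @param value Numeric value.
#' @param unit One of `"px"`, `"cm"`, `"inch"`, `"deg"`.
#' @inheritParams deg_to_px
#' @return Length in pixels.
#' @export
length_to_px <- function(value, unit, display) {
  switch(unit,
         px   = value,
         cm   = { check_display(display); value * display$pixels_per_cm },
         inch = { check_display(display); value * 2.54 * display$pixels_per_cm },
         deg  = deg_to_px(value, display),
         stop(sprintf("unknown unit '%s'; valid units are px, cm, inch, deg", unit),
              call. = FALSE))
}

#' Convert a duration in seconds to a whole number of frames
#'
#' Rounds to the nearest frame, ties away from zero, which minimizes the
#' absolute duration error of the realized scene.
#'
#' @param t Duration in seconds (>= 0).
#' @param refresh_rate Refresh rate in Hz (> 0).
#' @return Integer frame count.
#' @export
seconds_to_frames <- function(t, refresh_rate) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0", call. = FALSE)
  if (!is.finite(refresh_rate) || refresh_rate <= 0)
    stop("`refresh_rate` must be > 0", call. = FALSE)
  as.integer(floor(t * refresh_rate + 0.5))
}

#' Frame budget in milliseconds for a refresh rate
#'
#' The time available to compute one frame: 1000/refresh, reported rounded
#' to two decimals (16.67 ms at 60 Hz, 8.33 ms at 120 Hz).
#'
#' @inheritParams seconds_to_frames
#' @return Duration in ms, rounded to 2 decimals.
#' @export
frame_duration_ms <- function(refresh_rate) {
  if (!is.finite(refresh_rate) || refresh_rate <= 0)
    stop("`refresh_rate` must be > 0", call. = FALSE)
  round(1000 / refresh_rate, 2)
}

#' Convert a luminance fraction to cd/m^2 for a device
#'
#' Luminance in test files is a fraction of the device's maximum
#' brightness; the profile's `max_luminance` converts it to cd/m^2.
#'
#' @param fraction Luminance fraction in \[0, 1\].
#' @inheritParams deg_to_px
#' @return Luminance in cd/m^2.
#' @export
luminance_fraction_to_cd <- function(fraction, display) {
  check_display(display)
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("`fraction` must be within [0, 1]", call. = FALSE)
  fraction * display$max_luminance
}

# cycles/degree -> cycles/px at the display's center (chord of 1 degree)
cpd_to_cycles_per_px <- function(cpd, display) {
  cpd / deg_to_px(1, display)
}
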