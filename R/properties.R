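#' Property values: constants, timelines and per-trial variables
#'
#' Every stimulus property holds one of three value modes. A *constant* is a
#' scalar or short tuple (e.g. an RGB triple). A *timeline* changes over the
#' course of a scene, either linearly between two endpoints or sinusoidally
#' about a baseline. A *variable* takes its value per trial from a bound
#' numeric list (see [variable_binding()]).
#'
#' Units: a property may carry a `unit` tag (`"px"`, `"cm"`, `"inch"`,
#' `"deg"`, `"s"`, `"frames"`, `"rad"`, `"cpd"`, `"fraction"`); the renderer
#' converts spatial units to pixels and temporal units to frames through the
#' display profile.
#'
#' @param value Scalar or numeric tuple.
#' @param unit Optional unit tag.
#' @return A `property_value` object.
#' @name property-values
NULL

known_units <- c("px", "cm", "inch", "deg", "s", "frames", "rad", "cpd", "fraction")

#' @rdname property-values
#' @export
property_constant <- function(value, unit = NULL) {
  new_property(list(mode = "constant", value = value, unit = unit))
}

#' @rdname property-values
#' @param start_value,end_value Endpoints of a linear timeline (reached at
#'   the first and last frame of the scene).
#' @export
property_timeline_linear <- function(start_value, end_value, unit = NULL) {
  new_property(list(mode = "timeline", kind = "linear",
                    start_value = start_value, end_value = end_value,
                    unit = unit))
}

#' @rdname property-values
#' @param amplitude,frequency,phase Sinusoidal modulation about
#'   `start_value`: `start_value + amplitude * sin(2*pi*frequency*t + phase)`
#'   with `t` the scene time in seconds.
#' @export
property_timeline_sinusoidal <- function(start_value, amplitude, frequency,
                                         phase = 0, unit = NULL) {
  new_property(list(mode = "timeline", kind = "sinusoidal",
                    start_value = start_value, amplitude = amplitude,
                    frequency = frequency, phase = phase, unit = unit))
}

#' @rdname property-values
#' @param variable Name of the variable-binding target that supplies the
#'   per-trial value (e.g. `"scene2_object1_gratingRotation"`).
#' @export
property_variable <- function(variable, unit = NULL) {
  new_property(list(mode = "variable", variable = variable, unit = unit))
}

new_property <- function(x) {
  if (!is.null(x$unit) && !x$unit %in% known_units)
    stop(sprintf("unknown unit '%s'; valid units: %s", x$unit,
                 paste(known_units, collapse = ", ")), call. = FALSE)
  structure(x, class = "property_value")
}

is_property <- function(x) inherits(x, "property_value")

# Coerce a bare number/tuple given in a stimulus definition to a constant.
as_property <- function(x) {
  if (is_property(x)) return(x)
  if (is.numeric(x) || is.character(x) || is.logical(x))
    return(property_constant(x))
  stop("property must be a property_value or a bare constant", call. = FALSE)
}

#' Resolve a stimulus property at one frame of one trial
#'
#' @param stim A [stimulus_spec()].
#' @param prop Property name present on `stim`.
#' @param bindings Named list mapping variable targets to this trial's
#'   values (from the trial plan).
#' @param ctx Frame context: a list with `frame` (0-based frame index),
#'   `total_frames` and `refresh_rate`.
#' @return The resolved scalar or tuple, in the property's declared unit.
#' @export
resolve_property <- function(stim, prop, bindings = list(),
                             ctx = list(frame = 0L, total_frames = 1L,
                                        refresh_rate = 60)) {
  pv <- stim$properties[[prop]]
  if (is.null(pv))
    stop(sprintf("stimulus '%s' has no property '%s'", stim$name, prop),
         call. = FALSE)
  switch(pv$mode,
    constant = pv$value,
    variable = {
      v <- bindings[[pv$variable]]
      if (is.null(v))
        stop(sprintf("variable '%s' has no value assigned for this trial",
                     pv$variable), call. = FALSE)
      v
    },
    timeline = {
      f <- ctx$frame
      if (identical(pv$kind, "linear")) {
        n <- ctx$total_frames
        frac <- if (n <= 1L) 0 else f / (n - 1)
        pv$start_value + (pv$end_value - pv$start_value) * frac
      } else {
        t <- f / ctx$refresh_rate
        pv$start_value + pv$amplitude * sin(2 * pi * pv$frequency * t + pv$phase)
      }
    },
    stop(sprintf("unknown property mode '%s'", pv$mode), call. = FALSE))
}

# Resolve and convert a spatial property to px; temporal to frames.
resolve_px <- function(stim, prop, bindings, ctx, display, default = NULL) {
  if (is.null(stim$properties[[prop]])) {
    if (is.null(default)) return(NULL)
    return(default)
  }
  v <- resolve_property(stim, prop, bindings, ctx)
  u <- stim$properties[[prop]]$unit
  if (is.null(u) || u %in% c("rad", "fraction")) return(v)
  if (u == "cpd") return(cpd_to_cycles_per_px(v, display))
  if (u == "s") return(seconds_to_frames(v, ctx$refresh_rate))
  if (u == "frames") return(v)
  length_to_px(v, u, display)
}
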