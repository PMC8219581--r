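#' The declarative test hierarchy
#'
#' A test is a collection of sections; each section is a sequence of scenes
#' presented `repetitions` times (typically one section = one trial type);
#' each scene presents stimuli simultaneously and may collect a response.
#' Numeric lists plus variable bindings make chosen stimulus properties vary
#' across trials under a selection method (fixed, all values in random
#' order, random with replacement, or adaptive staircase).
#'
#' @name test-model
NULL

stimulus_types <- c("patch", "gradient", "grating", "checkerboard_rect",
                    "checkerboard_radial", "dots_linear", "dots_radial",
                    "dots_expansive", "text", "image", "tone", "noise",
                    "audio_file")
auditory_types <- c("tone", "noise", "audio_file")
stimulus_shapes <- c("rectangle", "ellipse", "cross")
selection_methods <- c("fixed", "all_values_random_order",
                       "random_with_replacement", "adaptive")
response_kinds <- c("left_or_right", "tap_regions", "touch_path", "keyboard")

general_props <- c("duration", "start_time", "position_x", "position_y",
                   "orientation", "size_x", "size_y", "noise_filter",
                   "color", "contrast")
type_props <- list(
  patch = character(0),
  gradient = c("color2"),
  grating = c("spatial_frequency", "phase", "envelope_sigma",
              "carrier_contrast_mod_sigma", "gratingRotation",
              "mean_luminance"),
  checkerboard_rect = c("check_w", "check_h", "color2"),
  checkerboard_radial = c("n_sectors", "ring_width", "color2"),
  dots_linear = c("n_dots", "dot_radius", "dot_speed", "dot_direction",
                  "coherence", "dot_lifetime"),
  dots_radial = c("n_dots", "dot_radius", "dot_speed", "dot_direction",
                  "coherence", "dot_lifetime"),
  dots_expansive = c("n_dots", "dot_radius", "dot_speed", "dot_direction",
                     "coherence", "dot_lifetime"),
  text = c("text_string", "text_scale"),
  image = c("file_path"),
  tone = c("tone_frequency", "amplitude", "ramp"),
  noise = c("amplitude"),
  audio_file = c("file_path", "amplitude"))

#' Define a stimulus
#'
#' @param name Unique stimulus name.
#' @param type One of the stimulus templates: `r paste0('"', stimulus_types, '"', collapse = ", ")`.
#' @param shape Aperture shape for visual stimuli: rectangle, ellipse or
#'   cross.
#' @param properties Named list of [property-values] (bare numbers are
#'   promoted to constants). Property names must be general properties or
#'   properties specific to `type`.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(name, type, shape = "rectangle", properties = list()) {
  if (!type %in% stimulus_types)
    stop(sprintf("unknown stimulus type '%s'", type), call. = FALSE)
  if (!shape %in% stimulus_shapes)
    stop(sprintf("unknown shape '%s'", shape), call. = FALSE)
  properties <- lapply(properties, as_property)
  structure(list(name = name, type = type, shape = shape,
                 properties = properties),
            class = "stimulus_spec")
}

#' Define a scene
#'
#' @param name Scene name (unique within its section).
#' @param duration Scene duration: a number (seconds) or a list
#'   `list(value =, unit = "s"|"frames")`.
#' @param objects Character vector of stimulus names, in draw order.
#' @param response A [response_spec()] or `NULL`.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(name, duration, objects = character(), response = NULL) {
  if (is.numeric(duration)) duration <- list(value = duration, unit = "s")
  structure(list(name = name, duration = duration,
                 objects = as.character(objects), response = response),
            class = "scene_spec")
}

#' Define a response collector for a scene
#'
#' `left_or_right` splits the screen into two half-screen tap regions and
#' maps each side to a numeric value (the classic two-alternative layout).
#'
#' @param kind One of `r paste0('"', response_kinds, '"', collapse = ", ")`.
#' @param values Named list mapping outcomes to recorded values, e.g.
#'   `list(left = -1, right = 1)`.
#' @param timeout Response window in seconds, or `NULL` for the full scene.
#' @return A `response_spec` object.
#' @export
response_spec <- function(kind = "left_or_right",
                          values = list(left = -1, right = 1),
                          timeout = NULL) {
  if (!kind %in% response_kinds)
    stop(sprintf("unknown response kind '%s'", kind), call. = FALSE)
  structure(list(kind = kind, values = values, timeout = timeout),
            class = "response_spec")
}

#' Define a section (a trial type)
#'
#' @param name Unique section name.
#' @param scenes List of [scene_spec()] objects, run in order each trial.
#' @param repetitions Number of trial repetitions (>= 1).
#' @param variables List of [variable_binding()] objects.
#' @param next_section Name of the section run after this one, or `"END"`.
#' @return A `section_spec` object.
#' @export
section_spec <- function(name, scenes, repetitions = 1L, variables = list(),
                         next_section = "END") {
  structure(list(name = name, scenes = scenes,
                 repetitions = as.integer(repetitions),
                 variables = variables, next_section = next_section),
            class = "section_spec")
}

#' Define a named list of numeric values
#'
#' @param name Unique list name.
#' @param values Numeric vector (non-empty).
#' @return A `numeric_list` object.
#' @export
numeric_list <- function(name, values) {
  structure(list(name = name, values = as.numeric(values)),
            class = "numeric_list")
}

#' Build an evenly spaced numeric list
#'
#' Inclusive endpoints; `n = 1` returns just `first`.
#'
#' @param first,last Endpoints.
#' @param n Number of values (>= 1).
#' @param name Name for the resulting list.
#' @return A [numeric_list()].
#' @examples
#' make_linear_sequence(-0.03, 0.03, 7)$values
#' @export
make_linear_sequence <- function(first, last, n, name = "sequence") {
  if (!is.finite(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  v <- if (n == 1) first else seq(first, last, length.out = n)
  numeric_list(name, v)
}

#' Bind a stimulus property to a list of per-trial values
#'
#' The target path uses 1-based scene and object indices within the
#' section, e.g. `"scene2_object1_gratingRotation"`: property
#' `gratingRotation` of the first object of the second scene.
#'
#' @param target Target path string.
#' @param list Name of the [numeric_list()] supplying values (may be `NULL`
#'   for adaptive bindings, which generate values from the staircase).
#' @param selection_method One of `r paste0('"', selection_methods, '"', collapse = ", ")`.
#' @param adaptive_config A [staircase_config()] (required when
#'   `selection_method = "adaptive"`).
#' @return A `variable_binding` object.
#' @export
variable_binding <- function(target, list = NULL,
                             selection_method = "all_values_random_order",
                             adaptive_config = NULL) {
  if (!selection_method %in% selection_methods)
    stop(sprintf("unknown selection method '%s'", selection_method),
         call. = FALSE)
  structure(base::list(target = target, list = list,
                       selection_method = selection_method,
                       adaptive_config = adaptive_config),
            class = "variable_binding")
}

#' Assemble a test
#'
#' @param name Test name.
#' @param settings List with `display` (a [display_profile()]),
#'   `audio_rate` (Hz, default 44100), `av_offset_ms` (signed audiovisual
#'   onset correction, default 0) and `rng_seed`.
#' @param stimuli List of [stimulus_spec()] objects.
#' @param sections List of [section_spec()] objects.
#' @param lists List of [numeric_list()] objects.
#' @param first_section Name of the section the run starts at.
#' @return A `stim_test` object.
#' @export
stim_test <- function(name, settings, stimuli, sections, lists = list(),
                      first_section = sections[[1]]$name) {
  settings$audio_rate <- settings$audio_rate %||% 44100
  settings$av_offset_ms <- settings$av_offset_ms %||% 0
  settings$rng_seed <- settings$rng_seed %||% 1L
  structure(list(name = name, settings = settings, stimuli = stimuli,
                 sections = sections, lists = lists,
                 first_section = first_section),
            class = "stim_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stim_test <- function(x, ...) {
  cat(sprintf("<stim_test> '%s'\n", x$name))
  cat(sprintf("  %d stimuli, %d section(s), %d list(s); first section '%s'\n",
              length(x$stimuli), length(x$sections), length(x$lists),
              x$first_section))
  cat(sprintf("  display: %s (%dx%d @ %g Hz), audio %g Hz\n",
              x$settings$display$model_name, x$settings$display$width_px,
              x$settings$display$height_px, x$settings$display$refresh_rate,
              x$settings$audio_rate))
  invisible(x)
}

find_by_name <- function(lst, name) {
  for (el in lst) if (identical(el$name, name)) return(el)
  NULL
}

# "scene2_object1_gratingRotation" -> list(scene = 2, object = 1, prop = ...)
parse_target <- function(target) {
  m <- regmatches(target, regexec("^scene([0-9]+)_object([0-9]+)_(.+)$", target))[[1]]
  if (length(m) != 4L) return(NULL)
  list(scene = as.integer(m[2]), object = as.integer(m[3]), prop = m[4])
}

#' Validate a test
#'
#' Checks every structural invariant of the hierarchy: unique names,
#' resolvable references (first section, scene objects, variable targets,
#' list names), positive repetitions and durations, property names legal
#' for each stimulus type, well-formed property values, and staircase
#' configuration present for adaptive bindings.
#'
#' @param test A [stim_test()].
#' @return A data frame of issues with columns `path` and `message`;
#'   zero rows if the test is valid.
#' @export
validate_test <- function(test) {
  issues <- list()
  add <- function(path, message)
    issues[[length(issues) + 1L]] <<- list(path = path, message = message)

  if (!inherits(test, "stim_test")) {
    add("", "not a stim_test object")
    return(issues_df(issues))
  }
  if (is.null(test$sections) || length(test$sections) == 0L)
    add("sections", "test has no sections")
  if (is.null(test$settings$display)) {
    add("settings.display", "missing display profile")
  } else {
    ok <- tryCatch({ check_display(test$settings$display); TRUE },
                   error = function(e) { add("settings.display", conditionMessage(e)); FALSE })
  }
  for (nm in c("stimuli", "sections", "lists")) {
    nms <- vapply(test[[nm]], function(x) x$name %||% "", character(1))
    dup <- unique(nms[duplicated(nms)])
    for (d in dup) add(nm, sprintf("duplicate name '%s'", d))
  }
  if (length(test$sections) > 0L &&
      is.null(find_by_name(test$sections, test$first_section)))
    add("first_section",
        sprintf("first_section '%s' does not name an existing section",
                test$first_section %||% "<missing>"))

  for (st in test$stimuli) {
    base <- sprintf("stimuli.%s", st$name)
    if (!st$type %in% stimulus_types) {
      add(base, sprintf("unknown type '%s'", st$type)); next
    }
    allowed <- c(general_props, type_props[[st$type]])
    for (pn in names(st$properties)) {
      pv <- st$properties[[pn]]
      if (!pn %in% allowed)
        add(sprintf("%s.%s", base, pn),
            sprintf("property '%s' is not valid for type '%s'", pn, st$type))
      if (!is_property(pv))
        add(sprintf("%s.%s", base, pn), "not a property_value")
      else if (!pv$mode %in% c("constant", "timeline", "variable"))
        add(sprintf("%s.%s", base, pn),
            sprintf("unknown property mode '%s'", pv$mode))
    }
  }

  for (sec in test$sections) {
    base <- sprintf("sections.%s", sec$name)
    if (is.null(sec$repetitions) || !is.finite(sec$repetitions) ||
        sec$repetitions < 1L)
      add(paste0(base, ".repetitions"), "repetitions must be >= 1")
    if (length(sec$scenes) == 0L)
      add(paste0(base, ".scenes"), "section has no scenes")
    if (!identical(sec$next_section, "END") &&
        is.null(find_by_name(test$sections, sec$next_section)))
      add(paste0(base, ".next_section"),
          sprintf("next_section '%s' does not exist", sec$next_section))
    for (sc in sec$scenes) {
      sbase <- sprintf("%s.%s", base, sc$name)
      d <- sc$duration
      if (is.null(d$value) || !is.finite(d$value) || d$value <= 0)
        add(paste0(sbase, ".duration"), "duration must be > 0")
      else if (!d$unit %in% c("s", "frames"))
        add(paste0(sbase, ".duration"),
            sprintf("duration unit must be 's' or 'frames', not '%s'", d$unit))
      for (ob in sc$objects)
        if (is.null(find_by_name(test$stimuli, ob)))
          add(paste0(sbase, ".objects"),
              sprintf("object '%s' does not name a stimulus", ob))
      if (!is.null(sc$response) && !sc$response$kind %in% response_kinds)
        add(paste0(sbase, ".response"),
            sprintf("unknown response kind '%s'", sc$response$kind))
    }
    for (vb in sec$variables) {
      vbase <- sprintf("%s.variables.%s", base, vb$target %||% "<missing>")
      tgt <- parse_target(vb$target %||% "")
      if (is.null(tgt)) {
        add(vbase, "target must look like 'scene<K>_object<J>_<property>'")
        next
      }
      if (tgt$scene > length(sec$scenes)) {
        add(vbase, sprintf("scene index %d out of range", tgt$scene))
        next
      }
      sc <- sec$scenes[[tgt$scene]]
      if (tgt$object > length(sc$objects)) {
        add(vbase, sprintf("object index %d out of range", tgt$object))
        next
      }
      st <- find_by_name(test$stimuli, sc$objects[[tgt$object]])
      if (!is.null(st)) {
        pv <- st$properties[[tgt$prop]]
        if (is.null(pv))
          add(vbase, sprintf("stimulus '%s' has no property '%s'",
                             st$name, tgt$prop))
        else if (!identical(pv$mode, "variable"))
          add(vbase, sprintf("property '%s' of '%s' is not in variable mode",
                             tgt$prop, st$name))
      }
      if (identical(vb$selection_method, "adaptive")) {
        if (is.null(vb$adaptive_config))
          add(vbase, "adaptive selection requires an adaptive_config")
      } else if (is.null(vb$list) ||
                 is.null(find_by_name(test$lists, vb$list))) {
        add(vbase, sprintf("list '%s' does not exist", vb$list %||% "<missing>"))
      }
    }
  }
  issues_df(issues)
}

issues_df <- function(issues) {
  if (length(issues) == 0L)
    return(data.frame(path = character(), message = character(),
                      stringsAsFactors = FALSE))
  data.frame(path = vapply(issues, `[[`, "", "path"),
             message = vapply(issues, `[[`, "", "message"),
             stringsAsFactors = FALSE)
}
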