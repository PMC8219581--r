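#' Read and write the JSON test-description format
#'
#' Tests are stored as UTF-8 JSON (extension `.stimulitest` or `.json`)
#' with top-level keys `schema_version`, `name`, `settings`, `stimuli`,
#' `sections`, `lists` and `first_section`; all cross-references are by
#' name. The format is deliberately plain so a test can be written or
#' edited in any text editor.
#'
#' @name test-io
NULL

schema_version <- "1"

#' Parse a JSON test description
#'
#' @param json_text JSON text (a single string) or a length-1 path handled
#'   by [read_test()].
#' @return A validated [stim_test()]. Parsing fails with a descriptive
#'   error on malformed JSON, on missing required keys, and on any
#'   dangling reference reported by [validate_test()].
#' @export
parse_test <- function(json_text) {
  raw <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON: ", conditionMessage(e), call. = FALSE))
  test <- build_test(raw)
  iss <- validate_test(test)
  if (nrow(iss) > 0L)
    stop("invalid test description:\n",
         paste(sprintf("  %s: %s", iss$path, iss$message), collapse = "\n"),
         call. = FALSE)
  test
}

#' Read a test from a `.stimulitest` / `.json` file
#'
#' @param path File path.
#' @return A validated [stim_test()].
#' @export
read_test <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  parse_test(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                   collapse = "\n"))
}

build_test <- function(raw) {
  if (is.null(raw$sections))
    stop("invalid test description:\n  sections: test has no sections",
         call. = FALSE)
  disp <- raw$settings$display
  if (is.null(disp))
    stop("invalid test description:\n  settings.display: missing display profile",
         call. = FALSE)
  display <- display_profile(disp$width_px, disp$height_px, disp$pixels_per_cm,
                             disp$refresh_rate %||% 60,
                             disp$max_luminance %||% 500,
                             disp$viewing_distance %||% 57.3,
                             disp$model_name %||% "generic")
  stimuli <- lapply(raw$stimuli %||% list(), build_stimulus)
  sections <- lapply(seq_along(raw$sections), function(i)
    build_section(raw$sections[[i]], i, length(raw$sections), raw$sections))
  lists <- lapply(raw$lists %||% list(), function(l)
    numeric_list(l$name, unlist(l$values)))
  stim_test(
    name = raw$name %||% "unnamed",
    settings = list(display = display,
                    audio_rate = raw$settings$audio_rate %||% 44100,
                    av_offset_ms = raw$settings$av_offset_ms %||% 0,
                    rng_seed = raw$settings$rng_seed %||% 1L),
    stimuli = stimuli, sections = sections, lists = lists,
    first_section = raw$first_section %||% raw$sections[[1]]$name)
}

build_stimulus <- function(s) {
  props <- lapply(s$properties %||% list(), build_property)
  stimulus_spec(s$name, s$type %||% "patch", s$shape %||% "rectangle", props)
}

build_property <- function(p) {
  if (!is.list(p)) return(property_constant(unlist(p)))
  unit <- p$unit
  switch(p$mode %||% "constant",
    constant = property_constant(unlist(p$value), unit),
    variable = property_variable(p$variable, unit),
    timeline = if (identical(p$kind, "sinusoidal"))
      property_timeline_sinusoidal(p$start_value, p$amplitude, p$frequency,
                                   p$phase %||% 0, unit)
    else
      property_timeline_linear(p$start_value, p$end_value, unit),
    stop(sprintf("unknown property mode '%s'", p$mode), call. = FALSE))
}

build_section <- function(sec, index, n_sections, raw_sections) {
  scenes <- lapply(sec$scenes %||% list(), function(sc)
    scene_spec(sc$name,
               if (is.list(sc$duration)) sc$duration else as.numeric(sc$duration %||% 1),
               unlist(sc$objects %||% character()),
               if (is.null(sc$response)) NULL else
                 response_spec(sc$response$kind %||% "left_or_right",
                               sc$response$values %||% list(left = -1, right = 1),
                               sc$response$timeout)))
  vars <- lapply(sec$variables %||% list(), function(v)
    variable_binding(v$target, v$list,
                     v$selection_method %||% "all_values_random_order",
                     if (is.null(v$adaptive_config)) NULL else
                       do.call(staircase_config, v$adaptive_config)))
  # default chaining: next section in file order, END after the last
  default_next <- if (index < n_sections) raw_sections[[index + 1L]]$name else "END"
  section_spec(sec$name, scenes, sec$repetitions %||% 1L, vars,
               sec$next_section %||% default_next)
}

#' Serialize a test to JSON text
#'
#' Key order is fixed, so serializing the same test twice yields
#' byte-identical text; `parse_test(serialize_test(x))` is structurally
#' the identity.
#'
#' @param test A valid [stim_test()].
#' @param pretty Pretty-print the JSON (default TRUE).
#' @return A JSON string with a `schema_version` field.
#' @export
serialize_test <- function(test, pretty = TRUE) {
  iss <- validate_test(test)
  if (nrow(iss) > 0L)
    stop("refusing to serialize an invalid test (see validate_test())",
         call. = FALSE)
  d <- test$settings$display
  out <- list(
    schema_version = schema_version,
    name = test$name,
    settings = list(
      display = list(model_name = d$model_name, width_px = d$width_px,
                     height_px = d$height_px, pixels_per_cm = d$pixels_per_cm,
                     refresh_rate = d$refresh_rate,
                     max_luminance = d$max_luminance,
                     viewing_distance = d$viewing_distance),
      audio_rate = test$settings$audio_rate,
      av_offset_ms = test$settings$av_offset_ms,
      rng_seed = test$settings$rng_seed),
    stimuli = lapply(test$stimuli, serialize_stimulus),
    sections = lapply(test$sections, serialize_section),
    lists = lapply(test$lists, function(l)
      list(name = l$name, values = as.list(l$values))),
    first_section = test$first_section)
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = pretty))
}

serialize_stimulus <- function(s) {
  list(name = s$name, type = s$type, shape = s$shape,
       properties = lapply(s$properties, serialize_property))
}

serialize_property <- function(p) {
  out <- switch(p$mode,
    constant = list(mode = "constant",
                    value = if (length(p$value) > 1L) as.list(p$value) else p$value),
    variable = list(mode = "variable", variable = p$variable),
    timeline = if (identical(p$kind, "sinusoidal"))
      list(mode = "timeline", kind = "sinusoidal",
           start_value = p$start_value, amplitude = p$amplitude,
           frequency = p$frequency, phase = p$phase)
    else
      list(mode = "timeline", kind = "linear",
           start_value = p$start_value, end_value = p$end_value))
  if (!is.null(p$unit)) out$unit <- p$unit
  out
}

serialize_section <- function(sec) {
  list(name = sec$name,
       repetitions = sec$repetitions,
       scenes = lapply(sec$scenes, function(sc) {
         out <- list(name = sc$name,
                     duration = list(value = sc$duration$value,
                                     unit = sc$duration$unit),
                     objects = as.list(sc$objects))
         out$response <- if (is.null(sc$response)) NULL else
           list(kind = sc$response$kind, values = sc$response$values,
                timeout = sc$response$timeout)
         out
       }),
       variables = lapply(sec$variables, function(v) {
         out <- list(target = v$target, list = v$list,
                     selection_method = v$selection_method)
         out$adaptive_config <- if (is.null(v$adaptive_config)) NULL else
           unclass(v$adaptive_config)
         out
       }),
       next_section = sec$next_section)
}

#' Write a test to a file
#'
#' @param test A valid [stim_test()].
#' @param path Output path (`.stimulitest` or `.json`).
#' @return `path`, invisibly.
#' @export
write_test <- function(test, path) {
  writeLines(serialize_test(test), path, useBytes = TRUE)
  invisible(path)
}
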