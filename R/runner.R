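#' Responders: simulated observers and scripted replays
#'
#' A responder stands in for the touchscreen. An *observer responder*
#' wraps a [psychometric_observer()] and answers left/right according to
#' its psychometric function, at a fixed latency (by default the last
#' frame of the response scene). A *scripted responder* replays an exact
#' list of sides and response frames, trial by trial.
#'
#' @param observer A [psychometric_observer()].
#' @param latency_frames Frame index (0-based) at which the observer
#'   responds, or `NULL` for the scene's final frame.
#' @return A responder object.
#' @export
observer_responder <- function(observer, latency_frames = NULL) {
  structure(list(type = "observer", observer = observer,
                 latency_frames = latency_frames),
            class = "responder")
}

#' @rdname observer_responder
#' @param sides Character vector of `"left"`/`"right"` answers, one per
#'   trial (`NA` for no response).
#' @param frames Integer vector of response frames (0-based), recycled;
#'   default 0 (respond at the first frame of the response scene).
#' @export
scripted_responder <- function(sides, frames = 0L) {
  structure(list(type = "scripted", sides = sides,
                 frames = rep_len(as.integer(frames), length(sides))),
            class = "responder")
}

scene_total_frames <- function(scene, refresh_rate) {
  d <- scene$duration
  n <- if (identical(d$unit, "frames")) as.integer(d$value)
       else seconds_to_frames(d$value, refresh_rate)
  max(1L, n)
}

#' Run one scene of one trial
#'
#' Renders frames 0..N-1, querying the responder once per frame. A
#' left/right response is a simulated tap: a tap left of the vertical
#' midline maps to the `left` value of the scene's [response_spec()], the
#' right half to `right`. The first response ends the scene;
#' `response_time` is `frame / refresh_rate`, so its resolution is one
#' frame.
#'
#' @param scene A [scene_spec()].
#' @param stimuli The test's stimulus list (for object lookup).
#' @param bindings Named list of this trial's variable values.
#' @param responder A responder (see [observer_responder()]) or `NULL`.
#' @param display A [display_profile()].
#' @param seed Integer seed governing this scene's stochastic rendering
#'   and the observer's decision.
#' @param correct_side `"left"`/`"right"`: which side is correct this
#'   trial (observers need it to err realistically).
#' @param stimulus_value The trial's stimulus value driving the observer.
#' @param trial_index Trial index (for scripted responders).
#' @param render Synthesize pixels (`TRUE`) or run trial logic only.
#' @param capture Keep every composited frame (implies `render`).
#' @return A list: `response_value`, `response_side`, `correct`,
#'   `response_time`, `frames_rendered`, `frame_times_ms`, and `frames`
#'   (list of frame buffers) when `capture = TRUE`.
#' @export
run_scene <- function(scene, stimuli, bindings = list(), responder = NULL,
                      display, seed = 0L, correct_side = "right",
                      stimulus_value = NA_real_, trial_index = 1L,
                      render = TRUE, capture = FALSE, n_frames_limit = NULL) {
  if (capture) render <- TRUE
  n_total <- scene_total_frames(scene, display$refresh_rate)
  n <- if (is.null(n_frames_limit)) n_total
       else min(n_total, as.integer(n_frames_limit))
  objects <- lapply(scene$objects, function(nm) find_by_name(stimuli, nm))
  visual <- vapply(objects, function(o) !o$type %in% auditory_types, logical(1))
  dot_states <- vector("list", length(objects))
  frames <- if (capture) vector("list", n) else NULL
  frame_times <- numeric(n)
  response_value <- NA_real_; response_side <- NA_character_
  correct <- NA; response_time <- NA_real_
  frames_rendered <- n

  # pre-drawn decision for observer responders: deterministic per scene seed
  obs_answer <- NULL
  if (!is.null(scene$response) && !is.null(responder)) {
    if (responder$type == "observer") {
      obs_answer <- simulate_response(responder$observer, stimulus_value,
                                      correct_side,
                                      seed = derive_seed(seed, 23))
      obs_frame <- responder$latency_frames %||% (n - 1L)
    } else {
      side <- responder$sides[min(trial_index, length(responder$sides))]
      obs_answer <- if (is.na(side)) NULL else
        list(correct = identical(side, correct_side), side = side)
      obs_frame <- responder$frames[min(trial_index, length(responder$frames))]
    }
  }

  ctx <- list(frame = 0L, total_frames = n_total,
              refresh_rate = display$refresh_rate)
  for (f in 0:(n - 1L)) {
    t0 <- proc.time()[["elapsed"]]
    if (render) {
      patches <- list()
      for (j in seq_along(objects)) {
        if (!visual[j]) next
        ctx$frame <- f
        ctx$dot_state <- dot_states[[j]]
        p <- render_stimulus_frame(objects[[j]], bindings, ctx, display,
                                   seed = derive_seed(seed, 31, j))
        ds <- attr(p, "dot_state")
        if (!is.null(ds)) dot_states[[j]] <- ds
        patches[[length(patches) + 1L]] <- p
      }
      if (capture) frames[[f + 1L]] <- composite_scene_frame(patches, display)
    }
    frame_times[f + 1L] <- (proc.time()[["elapsed"]] - t0) * 1000

    if (!is.null(obs_answer) && is.na(response_time) && f >= obs_frame) {
      tmo <- scene$response$timeout
      if (is.null(tmo) || f / display$refresh_rate <= tmo) {
        response_side <- obs_answer$side
        # simulated tap: left half of the screen vs right half
        tap_x <- if (identical(response_side, "left"))
          -display$width_px / 4 else display$width_px / 4
        side_key <- if (tap_x < 0) "left" else "right"
        response_value <- as.numeric(scene$response$values[[side_key]])
        correct <- obs_answer$correct
        response_time <- f / display$refresh_rate
        frames_rendered <- f + 1L
        frame_times <- frame_times[seq_len(frames_rendered)]
        break
      }
    }
  }
  list(response_value = response_value, response_side = response_side,
       correct = correct, response_time = response_time,
       frames_rendered = frames_rendered, frame_times_ms = frame_times,
       frames = frames, dot_states = dot_states)
}

#' Preview a single frame of a scene
#'
#' Returns exactly the frame buffer [run_scene()] produces at
#' `frame_index` under the same bindings and seed, replaying any
#' frame-to-frame state (dot fields) from the scene start.
#'
#' @param test A valid [stim_test()].
#' @param scene Scene name.
#' @param frame_index 0-based frame index (must be within the scene).
#' @param bindings Named list of variable values for the previewed trial.
#' @param seed Scene seed (defaults to the test's `rng_seed`).
#' @return A `frame_buffer`.
#' @export
preview_frame <- function(test, scene, frame_index, bindings = list(),
                          seed = test$settings$rng_seed) {
  sc <- NULL
  for (sec in test$sections) {
    sc <- find_by_name(sec$scenes, scene)
    if (!is.null(sc)) break
  }
  if (is.null(sc)) stop(sprintf("no scene named '%s'", scene), call. = FALSE)
  display <- test$settings$display
  n <- scene_total_frames(sc, display$refresh_rate)
  if (frame_index < 0 || frame_index >= n)
    stop(sprintf("frame %d out of range [0, %d)", frame_index, n),
         call. = FALSE)
  res <- run_scene(sc, test$stimuli, bindings, responder = NULL,
                   display = display, seed = seed, render = TRUE,
                   capture = TRUE, n_frames_limit = frame_index + 1L)
  res$frames[[frame_index + 1L]]
}

#' Dropped-frame accounting against the frame budget
#'
#' The frame budget is `1000 / refresh_rate` ms. A frame is dropped iff
#' its compute time strictly exceeds the budget (a frame finishing
#' exactly on budget still makes the refresh); each dropped frame is
#' reported with its duration.
#'
#' @param frame_times_ms Per-frame compute times in ms.
#' @param refresh_rate Refresh rate in Hz.
#' @return A `timing_report`: refresh rate, frame budget (ms), the raw
#'   times, a data frame of dropped frames (`frame`, 1-based, and
#'   `duration_ms`) and `percent_dropped`.
#' @export
timing_report <- function(frame_times_ms, refresh_rate) {
  if (any(frame_times_ms < 0)) stop("frame times must be >= 0", call. = FALSE)
  budget <- 1000 / refresh_rate
  idx <- which(frame_times_ms > budget)
  structure(list(
    refresh_rate = refresh_rate,
    frame_budget_ms = frame_duration_ms(refresh_rate),
    frame_times_ms = frame_times_ms,
    dropped_frames = data.frame(frame = idx,
                                duration_ms = frame_times_ms[idx]),
    percent_dropped = if (length(frame_times_ms) == 0L) 0 else
      100 * length(idx) / length(frame_times_ms)),
    class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("<timing_report> %g Hz (budget %.2f ms), %d frames\n",
              x$refresh_rate, x$frame_budget_ms, length(x$frame_times_ms)))
  cat(sprintf("  dropped: %d (%.2f%%)\n", nrow(x$dropped_frames),
              x$percent_dropped))
  invisible(x)
}

#' Execute a test end to end
#'
#' Starts at the test's first section and follows `next_section` chaining
#' until `END`. Constant-stimuli sections are expanded up front
#' ([expand_section_trials()]); adaptive sections are sequenced lazily
#' against the live staircase, feeding each response back. Every trial
#' runs its scenes in order with the trial's variable values bound; the
#' response scene's outcome makes one row of the results table. The run
#' is fully deterministic given the test and the seed.
#'
#' @param test A valid [stim_test()].
#' @param responder A responder (see [observer_responder()]).
#' @param seed Integer master seed (defaults to the test's `rng_seed`).
#' @param render Synthesize pixels on every frame (`TRUE`) or run trial
#'   logic only (`FALSE`, the fast headless default).
#' @return An object of class `stim_run`: `trials` (data frame),
#'   `settings_report` (named list), `timing` (a [timing_report()]) and
#'   `test_name`.
#' @export
run_test <- function(test, responder, seed = test$settings$rng_seed,
                     render = FALSE) {
  iss <- validate_test(test)
  if (nrow(iss) > 0L)
    stop("refusing to run an invalid test (see validate_test())", call. = FALSE)
  display <- test$settings$display
  rows <- list()
  all_times <- numeric()
  trial_global <- 0L
  sec_name <- test$first_section
  visited <- 0L

  while (!identical(sec_name, "END")) {
    visited <- visited + 1L
    if (visited > 10000L) stop("section chain did not terminate", call. = FALSE)
    sec <- find_by_name(test$sections, sec_name)
    adaptive <- length(sec$variables) > 0L &&
      identical(sec$variables[[1]]$selection_method, "adaptive")

    if (!adaptive) {
      plan <- expand_section_trials(sec, test$lists,
                                    seed = derive_seed(seed, 41, visited))
      targets <- setdiff(names(plan), c("trial_index", "section"))
      for (i in seq_len(nrow(plan))) {
        trial_global <- trial_global + 1L
        bindings <- as.list(plan[i, targets, drop = FALSE])
        res <- run_trial(test, sec, bindings, targets, responder, display,
                         seed, trial_global, render)
        all_times <- c(all_times, res$frame_times)
        rows[[trial_global]] <- res$row
      }
    } else {
      vb <- sec$variables[[1]]
      cfg <- vb$adaptive_config
      state <- staircase_init(cfg)
      max_trials <- 10000L
      while (!state$finished && nrow(state$history) < max_trials) {
        trial_global <- trial_global + 1L
        bindings <- stats::setNames(list(state$current_value), vb$target)
        res <- run_trial(test, sec, bindings, vb$target, responder, display,
                         seed, trial_global, render)
        all_times <- c(all_times, res$frame_times)
        correct <- isTRUE(res$row$correct)
        state <- staircase_next(state, cfg, correct)
        rows[[trial_global]] <- res$row
      }
    }
    sec_name <- sec$next_section
  }

  trials <- do.call(rbind, rows)
  trials$trial_index <- seq_len(nrow(trials))
  settings_report <- list(
    app_version = paste("stimkit", as.character(utils::packageVersion("stimkit"))),
    test = test$name,
    device_model = display$model_name,
    audio_rate = test$settings$audio_rate,
    screen_resolution = sprintf("%dx%d", display$width_px, display$height_px),
    frame_rate = display$refresh_rate,
    viewing_distance_cm = display$viewing_distance,
    av_offset_ms = test$settings$av_offset_ms,
    seed = seed)
  structure(list(trials = trials, settings_report = settings_report,
                 timing = timing_report(all_times, display$refresh_rate),
                 test_name = test$name),
            class = "stim_run")
}

run_trial <- function(test, sec, bindings, targets, responder, display,
                      seed, trial_global, render) {
  primary <- if (length(targets) > 0L) bindings[[targets[1]]] else NA_real_
  correct_side <- if (is.na(primary)) "right"
    else if (primary > 0) "right"
    else if (primary < 0) "left"
    else with_local_seed(derive_seed(seed, 43, trial_global),
                         sample(c("left", "right"), 1))
  frame_times <- numeric()
  out <- list(response_value = NA_real_, response_side = NA_character_,
              correct = NA, response_time = NA_real_)
  for (k in seq_along(sec$scenes)) {
    sc <- sec$scenes[[k]]
    r <- run_scene(sc, test$stimuli, bindings,
                   responder = if (is.null(sc$response)) NULL else responder,
                   display = display,
                   seed = derive_seed(seed, 47, trial_global, k),
                   correct_side = correct_side,
                   stimulus_value = primary,
                   trial_index = trial_global,
                   render = render)
    frame_times <- c(frame_times, r$frame_times_ms)
    if (!is.null(sc$response) && !is.na(r$response_time) && is.na(out$response_time))
      out <- r[c("response_value", "response_side", "correct", "response_time")]
  }
  row <- data.frame(trial_index = trial_global, section = sec$name,
                    stringsAsFactors = FALSE)
  for (tg in targets) row[[tg]] <- bindings[[tg]]
  row$response_value <- out$response_value
  row$response_side <- out$response_side
  row$correct <- out$correct
  row$response_time <- out$response_time
  list(row = row, frame_times = frame_times)
}

#' @export
print.stim_run <- function(x, ...) {
  cat(sprintf("<stim_run> '%s': %d trials\n", x$test_name, nrow(x$trials)))
  cat(sprintf("  %d frames, %d dropped (%.2f%%)\n",
              length(x$timing$frame_times_ms), nrow(x$timing$dropped_frames),
              x$timing$percent_dropped))
  if ("correct" %in% names(x$trials) && any(!is.na(x$trials$correct)))
    cat(sprintf("  proportion correct: %.3f\n",
                mean(x$trials$correct, na.rm = TRUE)))
  invisible(x)
}

#' Write the results bundle
#'
#' Writes the trial-wise table as `results.csv` (RFC 4180: comma
#' separated, header row, UTF-8) and the settings report as
#' `settings.txt` (`key: value` lines including audio rate, screen
#' resolution and frame rate). When the run carries a timing report it is
#' written as `timing.json`.
#'
#' @param run A `stim_run` from [run_test()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_results <- function(run, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  csv_path <- file.path(out_dir, "results.csv")
  txt_path <- file.path(out_dir, "settings.txt")
  utils::write.csv(run$trials, csv_path, row.names = FALSE)
  sr <- run$settings_report
  lines <- c(
    sprintf("app version: %s", sr$app_version),
    sprintf("test: %s", sr$test),
    sprintf("device model: %s", sr$device_model),
    sprintf("audio rate: %s", format(sr$audio_rate)),
    sprintf("screen resolution: %s", sr$screen_resolution),
    sprintf("frame rate: %s", format(sr$frame_rate)),
    sprintf("viewing distance cm: %s", format(sr$viewing_distance_cm)),
    sprintf("av offset ms: %s", format(sr$av_offset_ms)),
    sprintf("seed: %s", format(sr$seed)))
  writeLines(lines, txt_path)
  paths <- c(csv = csv_path, txt = txt_path)
  if (!is.null(run$timing)) {
    json_path <- file.path(out_dir, "timing.json")
    jsonlite::write_json(list(
      refresh_rate = run$timing$refresh_rate,
      frame_budget_ms = run$timing$frame_budget_ms,
      n_frames = length(run$timing$frame_times_ms),
      dropped_frames = run$timing$dropped_frames,
      percent_dropped = run$timing$percent_dropped),
      json_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, json = json_path)
  }
  paths
}
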