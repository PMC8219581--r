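#' Configure a transformed up-down staircase
#'
#' Transformed up-down rules: after `n_down` consecutive correct responses
#' the stimulus value decreases by `step_down`; after `n_up` consecutive
#' incorrect responses it increases by `step_up`. The 1-up/2-down rule
#' converges to the 70.7%-correct point (2^(-1/2)) of the psychometric
#' function, 1-up/3-down to 79.4% and 1-up/1-down to 50%. The staircase
#' stops after `n_reversals_stop` reversals of step direction.
#'
#' @param n_up,n_down Run lengths of the up/down rule.
#' @param step_up,step_down Step sizes (> 0), in stimulus units.
#' @param start_value Initial stimulus value.
#' @param n_reversals_stop Reversal count at which the staircase finishes
#'   (>= 2).
#' @param min_value,max_value Clamping bounds for the stimulus value.
#' @return A `staircase_config` object.
#' @export
staircase_config <- function(n_up = 1L, n_down = 2L, step_up, step_down,
                             start_value, n_reversals_stop = 8L,
                             min_value = -Inf, max_value = Inf) {
  if (step_up <= 0 || step_down <= 0)
    stop("step sizes must be > 0", call. = FALSE)
  if (n_reversals_stop < 2)
    stop("`n_reversals_stop` must be >= 2", call. = FALSE)
  structure(list(n_up = as.integer(n_up), n_down = as.integer(n_down),
                 step_up = step_up, step_down = step_down,
                 start_value = start_value,
                 n_reversals_stop = as.integer(n_reversals_stop),
                 min_value = min_value, max_value = max_value),
            class = "staircase_config")
}

#' Start a staircase
#'
#' @param config A [staircase_config()].
#' @return A `staircase_state` holding the current value, run counters,
#'   the reversal values recorded so far, the (value, response) history
#'   and a `finished` flag.
#' @export
staircase_init <- function(config) {
  structure(list(
    current_value = min(config$max_value,
                        max(config$min_value, config$start_value)),
    run_correct = 0L, run_incorrect = 0L,
    last_direction = 0L,
    reversals = numeric(),
    history = data.frame(value = numeric(), correct = logical()),
    finished = FALSE),
    class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Records the response at the current value, applies the up-down rule,
#' registers a reversal whenever the step direction changes, clamps the
#' value to the configured bounds, and marks the staircase finished once
#' the stop criterion is reached.
#'
#' @param state A `staircase_state`.
#' @param config The matching [staircase_config()].
#' @param correct Logical: was the response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_next <- function(state, config, correct) {
  if (state$finished)
    stop("staircase is finished; no further trials accepted", call. = FALSE)
  state$history <- rbind(state$history,
                         data.frame(value = state$current_value,
                                    correct = as.logical(correct)))
  direction <- 0L
  if (correct) {
    state$run_correct <- state$run_correct + 1L
    state$run_incorrect <- 0L
    if (state$run_correct >= config$n_down) {
      direction <- -1L
      state$run_correct <- 0L
    }
  } else {
    state$run_incorrect <- state$run_incorrect + 1L
    state$run_correct <- 0L
    if (state$run_incorrect >= config$n_up) {
      direction <- 1L
      state$run_incorrect <- 0L
    }
  }
  if (direction != 0L) {
    if (state$last_direction != 0L && direction != state$last_direction)
      state$reversals <- c(state$reversals, state$current_value)
    state$last_direction <- direction
    step <- if (direction > 0L) config$step_up else -config$step_down
    state$current_value <- min(config$max_value,
                               max(config$min_value,
                                   state$current_value + step))
    if (length(state$reversals) >= config$n_reversals_stop)
      state$finished <- TRUE
  }
  state
}

#' Threshold estimate from a staircase
#'
#' Arithmetic mean of the last `n_last_reversals` reversal values.
#'
#' @param state A `staircase_state`.
#' @param n_last_reversals How many of the most recent reversals to
#'   average.
#' @return The threshold estimate.
#' @export
staircase_estimate <- function(state, n_last_reversals) {
  k <- length(state$reversals)
  if (k < n_last_reversals)
    stop(sprintf("only %d reversals recorded; %d requested", k,
                 n_last_reversals), call. = FALSE)
  mean(state$reversals[(k - n_last_reversals + 1L):k])
}

#' Define a simulated psychometric observer
#'
#' The observer answers a trial correctly with probability
#' `P(correct) = guess + (1 - guess - lapse) * F(|value|; threshold, slope)`
#' where `F` is a logistic or cumulative-Gaussian sigmoid with `F(threshold)
#' = 0.5`. For a two-alternative task with `guess = 0.5`, performance at
#' the threshold value is therefore 75% correct; as the value grows,
#' performance approaches `1 - lapse`.
#'
#' @param threshold Stimulus magnitude at which `F = 0.5`.
#' @param slope Sigmoid slope (1/stimulus units).
#' @param guess_rate Lower asymptote (0.5 for 2AFC, 0 for yes/no).
#' @param lapse_rate Lapse rate in \[0, 1).
#' @param form `"logistic"` or `"cumulative_gaussian"`.
#' @return A `psychometric_observer` object.
#' @export
psychometric_observer <- function(threshold, slope, guess_rate = 0.5,
                                  lapse_rate = 0,
                                  form = c("logistic", "cumulative_gaussian")) {
  form <- match.arg(form)
  if (guess_rate < 0 || guess_rate > 1 || lapse_rate < 0 || lapse_rate >= 1)
    stop("guess_rate must be in [0,1], lapse_rate in [0,1)", call. = FALSE)
  structure(list(threshold = threshold, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 form = form),
            class = "psychometric_observer")
}

psychometric_F <- function(x, threshold, slope, form) {
  switch(form,
         logistic = stats::plogis(slope * (x - threshold)),
         cumulative_gaussian = stats::pnorm(slope * (x - threshold)))
}

#' Probability that an observer answers correctly
#'
#' @param observer A [psychometric_observer()].
#' @param stimulus_value Stimulus value(s); the sigmoid acts on the
#'   magnitude `|stimulus_value|`.
#' @return Probability (vector) of a correct response.
#' @export
p_correct <- function(observer, stimulus_value) {
  F <- psychometric_F(abs(stimulus_value), observer$threshold,
                      observer$slope, observer$form)
  observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) * F
}

#' Simulate one response from an observer
#'
#' Draws a correct/incorrect outcome with probability
#' [p_correct()] and, for left/right tasks, emits the corresponding side.
#'
#' @param observer A [psychometric_observer()].
#' @param stimulus_value The trial's stimulus value.
#' @param correct_side `"left"` or `"right"` (or `NULL` for tasks without
#'   sides).
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return A list with `correct` (logical) and `side` (character or
#'   `NULL`).
#' @export
simulate_response <- function(observer, stimulus_value, correct_side = NULL,
                              seed = NULL) {
  p <- p_correct(observer, stimulus_value)
  correct <- with_local_seed(seed, stats::runif(1) < p)
  side <- NULL
  if (!is.null(correct_side)) {
    other <- if (identical(correct_side, "left")) "right" else "left"
    side <- if (correct) correct_side else other
  }
  list(correct = correct, side = side)
}

#' Expand a section into a trial plan
#'
#' Method-of-constant-stimuli expansion. For each variable binding:
#' `fixed` repeats the list's first value; `all_values_random_order` runs
#' `repetitions` independent permutation blocks of the full list (so a
#' 7-value list with 20 repetitions yields 140 trials, each value
#' occurring exactly 20 times and exactly once per consecutive block of
#' 7); `random_with_replacement` draws each trial's value independently.
#' Sections whose bindings are adaptive are sequenced lazily by the
#' runner against the live staircase and are not expanded here.
#'
#' @param section A [section_spec()].
#' @param lists List of [numeric_list()] objects available to bindings.
#' @param seed Optional integer seed for a locally scoped RNG stream.
#' @return A data frame with columns `trial_index`, `section` and one
#'   column per bound variable target.
#' @export
expand_section_trials <- function(section, lists, seed = NULL) {
  if (any(vapply(section$variables, function(v)
    identical(v$selection_method, "adaptive"), logical(1))))
    stop("adaptive sections are sequenced lazily by the runner, not expanded",
         call. = FALSE)
  reps <- section$repetitions
  cols <- list()
  n_trials <- reps
  for (vb in section$variables) {
    nl <- find_by_name(lists, vb$list)
    if (is.null(nl))
      stop(sprintf("list '%s' not found", vb$list), call. = FALSE)
    if (identical(vb$selection_method, "all_values_random_order"))
      n_trials <- max(n_trials, length(nl$values) * reps)
  }
  with_local_seed(seed, {
    for (vb in section$variables) {
      nl <- find_by_name(lists, vb$list)
      v <- switch(vb$selection_method,
        fixed = rep(nl$values[1], n_trials),
        all_values_random_order = {
          blocks <- unlist(lapply(seq_len(ceiling(n_trials / length(nl$values))),
                                  function(i) sample(nl$values)))
          blocks[seq_len(n_trials)]
        },
        random_with_replacement = sample(nl$values, n_trials, replace = TRUE),
        stop(sprintf("unsupported selection method '%s'", vb$selection_method),
             call. = FALSE))
      cols[[vb$target]] <- v
    }
  })
  out <- data.frame(trial_index = seq_len(n_trials),
                    section = section$name,
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  out
}

#' Maximum-likelihood psychometric fit
#'
#' Fits `P(correct) = guess + (1 - guess - lapse) * F(value; threshold,
#' slope)` to trial-wise binary data under a binomial likelihood, with
#' guess and lapse fixed. The optimizer (Nelder-Mead over threshold and
#' log-slope) starts from a deterministic initial point, so refitting the
#' same data reproduces the same estimates.
#'
#' @param values Numeric stimulus magnitudes, one per trial.
#' @param correct Logical (or 0/1) responses, one per trial.
#' @param form `"logistic"` or `"cumulative_gaussian"`.
#' @param guess_rate,lapse_rate Fixed asymptotes.
#' @return An object of class `psychometric_fit` with components
#'   `threshold`, `slope`, `loglik`, `boundary` and the data; supports
#'   `print()`, `coef()`, `predict()` and `logLik()`.
#' @export
fit_psychometric <- function(values, correct,
                             form = c("logistic", "cumulative_gaussian"),
                             guess_rate = 0.5, lapse_rate = 0.01) {
  form <- match.arg(form)
  values <- abs(as.numeric(values))
  correct <- as.logical(correct)
  if (length(values) != length(correct))
    stop("`values` and `correct` must have equal length", call. = FALSE)
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct stimulus values", call. = FALSE)

  boundary <- FALSE
  if (all(correct) || all(!correct)) {
    warning("responses are all identical: estimates lie on the boundary; ",
            "reporting the midpoint of the stimulus range as threshold")
    boundary <- TRUE
    threshold <- mean(range(values))
    slope <- NA_real_
    ll <- 0
  } else {
    nll <- function(par) {
      thr <- par[1]; slo <- exp(par[2])
      p <- guess_rate + (1 - guess_rate - lapse_rate) *
        psychometric_F(values, thr, slo, form)
      p <- pmin(1 - 1e-9, pmax(1e-9, p))
      -sum(ifelse(correct, log(p), log(1 - p)))
    }
    spread <- max(diff(range(values)), 1e-6)
    start <- c(stats::median(values), log(4 / spread))
    fit <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    threshold <- fit$par[1]
    slope <- exp(fit$par[2])
    ll <- -fit$value
  }
  structure(list(threshold = threshold, slope = slope, loglik = ll,
                 form = form, guess_rate = guess_rate,
                 lapse_rate = lapse_rate, boundary = boundary,
                 data = data.frame(value = values, correct = correct)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> %s, %d trials\n", x$form, nrow(x$data)))
  cat(sprintf("  threshold %.5g, slope %.5g (guess %.3g, lapse %.3g fixed)\n",
              x$threshold, x$slope, x$guess_rate, x$lapse_rate))
  cat(sprintf("  log-likelihood %.3f%s\n", x$loglik,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(threshold = object$threshold, slope = object$slope)
}

#' @export
logLik.psychometric_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}

#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$value else abs(as.numeric(newdata))
  object$guess_rate + (1 - object$guess_rate - object$lapse_rate) *
    psychometric_F(v, object$threshold, object$slope, object$form)
}
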