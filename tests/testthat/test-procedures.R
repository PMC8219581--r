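test_that("all-values-random-order expands to per-block permutations", {
  sec <- section_spec("s", list(scene_spec("sc", 0.1, character())),
                      repetitions = 20L,
                      variables = list(variable_binding("scene1_object1_x",
                                                        "l7")))
  lists <- list(make_linear_sequence(-0.03, 0.03, 7, name = "l7"))
  plan <- expand_section_trials(sec, lists, seed = 1)
  expect_identical(nrow(plan), 140L)
  counts <- table(plan$scene1_object1_x)
  expect_true(all(counts == 20L))
  # each consecutive block of 7 trials is a permutation of the list
  vals <- sort(lists[[1]]$values)
  for (b in seq_len(20))
    expect_equal(sort(plan$scene1_object1_x[(7 * b - 6):(7 * b)]), vals)
  # different blocks are independently shuffled (not all identical)
  blocks <- matrix(plan$scene1_object1_x, nrow = 7)
  expect_gt(length(unique(apply(blocks, 2, paste, collapse = ","))), 1L)
})

test_that("fixed and with-replacement selection behave as documented", {
  lists <- list(numeric_list("l3", c(4, 5, 6)))
  sec1 <- section_spec("s", list(scene_spec("sc", 0.1, character())), 1L,
                       list(variable_binding("scene1_object1_x", "l3")))
  p1 <- expand_section_trials(sec1, lists, seed = 2)
  expect_equal(sort(p1$scene1_object1_x), c(4, 5, 6))

  secf <- section_spec("s", list(scene_spec("sc", 0.1, character())), 5L,
                       list(variable_binding("scene1_object1_x", "l3",
                                             "fixed")))
  pf <- expand_section_trials(secf, lists, seed = 3)
  expect_identical(pf$scene1_object1_x, rep(4, 5))

  secr <- section_spec("s", list(scene_spec("sc", 0.1, character())), 50L,
                       list(variable_binding("scene1_object1_x", "l3",
                                             "random_with_replacement")))
  pr <- expand_section_trials(secr, lists, seed = 4)
  expect_identical(nrow(pr), 50L)
  expect_true(all(pr$scene1_object1_x %in% c(4, 5, 6)))
  # same seed reproduces the plan
  expect_identical(expand_section_trials(secr, lists, seed = 4), pr)
})

test_that("the up-down rule steps, records reversals and clamps", {
  cfg <- staircase_config(1, 2, step_up = 1, step_down = 1, start_value = 10,
                          n_reversals_stop = 4, min_value = 0, max_value = 20)
  st <- staircase_init(cfg)
  # two consecutive correct: one step down, run reset
  st <- staircase_next(st, cfg, TRUE)
  expect_identical(st$current_value, 10)
  st <- staircase_next(st, cfg, TRUE)
  expect_identical(st$current_value, 9)
  expect_identical(st$run_correct, 0L)
  # a single incorrect steps up immediately and is the first reversal
  st <- staircase_next(st, cfg, FALSE)
  expect_identical(st$current_value, 10)
  expect_identical(st$reversals, 9)
  # value trace respects bounds
  cfg2 <- staircase_config(1, 1, 5, 5, start_value = 2, n_reversals_stop = 50,
                           min_value = 0, max_value = 8)
  st2 <- staircase_init(cfg2)
  set.seed(1)
  for (i in 1:200) {
    if (st2$finished) break
    st2 <- staircase_next(st2, cfg2, runif(1) < 0.5)
    expect_gte(st2$current_value, 0)
    expect_lte(st2$current_value, 8)
  }
  expect_error(staircase_config(1, 2, step_up = 0, step_down = 1,
                                start_value = 1), "> 0")
})

test_that("reversal counting is monotone and finishing locks the staircase", {
  cfg <- staircase_config(1, 1, 1, 1, start_value = 5, n_reversals_stop = 3)
  st <- staircase_init(cfg)
  prev <- 0L
  set.seed(2)
  while (!st$finished) {
    st <- staircase_next(st, cfg, runif(1) < 0.5)
    expect_gte(length(st$reversals), prev)
    prev <- length(st$reversals)
  }
  expect_gte(length(st$reversals), 3L)
  expect_error(staircase_next(st, cfg, TRUE), "finished")
})

test_that("staircase_estimate averages the last reversals", {
  st <- structure(list(reversals = c(8, 6, 8, 6)), class = "staircase_state")
  expect_identical(staircase_estimate(st, 4), 7)
  expect_identical(staircase_estimate(st, 2), 7)
  st2 <- structure(list(reversals = rep(3.5, 6)), class = "staircase_state")
  expect_identical(staircase_estimate(st2, 6), 3.5)
  expect_error(staircase_estimate(st, 5), "4 reversals")
})

test_that("the simulated observer follows its psychometric function", {
  obs <- psychometric_observer(threshold = 10, slope = 0.5, guess_rate = 0.5,
                               lapse_rate = 0)
  expect_equal(p_correct(obs, 10), 0.75)      # guess + 0.5 * F(threshold)
  expect_equal(p_correct(obs, 1e6), 1, tolerance = 1e-9)
  obs_lapse <- psychometric_observer(10, 0.5, 0.5, lapse_rate = 0.1)
  expect_equal(p_correct(obs_lapse, 1e6), 0.9, tolerance = 1e-9)
  # magnitude symmetry: the sigmoid acts on |value|
  expect_equal(p_correct(obs, -10), p_correct(obs, 10))
  r <- simulate_response(obs, 1e6, correct_side = "left", seed = 1)
  expect_true(r$correct)
  expect_identical(r$side, "left")
  expect_identical(simulate_response(obs, 1e6, "left", seed = 1), r)
  expect_error(psychometric_observer(1, 1, guess_rate = 2), "guess_rate")
})

test_that("a 1-up/2-down staircase tracks the 70.7%-correct point", {
  obs <- psychometric_observer(threshold = 10, slope = 0.5, guess_rate = 0,
                               lapse_rate = 0)
  # analytic 70.7% point of the logistic: threshold + log(p/(1-p))/slope
  p <- 2^(-1 / 2)
  x707 <- 10 + log(p / (1 - p)) / 0.5
  cfg <- staircase_config(1, 2, step_up = 1, step_down = 1, start_value = 20,
                          n_reversals_stop = 12, min_value = 0,
                          max_value = 40)
  ests <- vapply(1:40, function(s) {
    st <- staircase_init(cfg)
    k <- 0L
    while (!st$finished) {
      k <- k + 1L
      r <- simulate_response(obs, st$current_value, seed = s * 1000 + k)
      st <- staircase_next(st, cfg, r$correct)
    }
    staircase_estimate(st, 6)
  }, numeric(1))
  expect_lt(abs(median(ests) - x707), 2 * 1)  # within 2 step sizes
})

test_that("the psychometric fit is deterministic and recovers its generator", {
  # large-sample consistency: at 400 trials per level the MLE sits close
  # to the generating parameters
  values <- rep(c(0, 0.01, 0.02, 0.03), each = 400)
  obs <- tutorial_observer()
  set.seed(11)
  correct <- runif(length(values)) < p_correct(obs, values)
  fit <- fit_psychometric(values, correct, guess_rate = 0.5,
                          lapse_rate = 0.02)
  refit <- fit_psychometric(values, correct, guess_rate = 0.5,
                            lapse_rate = 0.02)
  expect_identical(coef(fit), coef(refit))
  expect_lt(abs(fit$threshold - 0.015) / 0.015, 0.25)
  expect_s3_class(fit, "psychometric_fit")
  expect_identical(length(coef(fit)), 2L)
  p <- predict(fit, c(0, 0.015, 1))
  expect_true(all(diff(p) > 0))
})

test_that("degenerate response data hits the boundary path with a warning", {
  expect_warning(
    fit <- fit_psychometric(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE)),
    "boundary")
  expect_identical(fit$threshold, 2.5)  # midpoint of the extreme values
  expect_true(fit$boundary)
  expect_error(fit_psychometric(c(1, 1), c(TRUE, FALSE)), "distinct")
})
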