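test_that("the tutorial test runs to a 140-row trial table", {
  test <- tutorial_test()
  run <- run_test(test, observer_responder(tutorial_observer()), seed = 1)
  expect_s3_class(run, "stim_run")
  expect_identical(nrow(run$trials), 140L)
  expect_true("scene2_object1_gratingRotation" %in% names(run$trials))
  counts <- table(run$trials$scene2_object1_gratingRotation)
  expect_identical(length(counts), 7L)
  expect_true(all(counts == 20L))
  expect_true(all(run$trials$response_value %in% c(-1, 1)))
})

test_that("runs are deterministic: same seed, byte-identical outputs", {
  test <- tutorial_test()
  resp <- observer_responder(tutorial_observer())
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  p1 <- write_results(run_test(test, resp, seed = 9), d1)
  p2 <- write_results(run_test(test, resp, seed = 9), d2)
  expect_identical(readLines(p1[["csv"]]), readLines(p2[["csv"]]))
  expect_identical(readLines(p1[["txt"]]), readLines(p2[["txt"]]))
  p3 <- write_results(run_test(test, resp, seed = 10),
                      file.path(tempdir(), "runC"))
  expect_false(identical(readLines(p1[["csv"]]), readLines(p3[["csv"]])))
  unlink(c(d1, d2, file.path(tempdir(), "runC")), recursive = TRUE)
})

test_that("a variable-free single-repetition section yields one row", {
  test <- tiny_test(repetitions = 1L)
  run <- run_test(test, observer_responder(tutorial_observer()), seed = 1)
  expect_identical(nrow(run$trials), 1L)
  expect_true(is.na(run$trials$response_value))  # scene has no response spec
})

test_that("scene execution honours durations, responses and timing", {
  d <- unit_display(refresh = 60)
  stim <- stimulus_spec("p", "patch", properties = list(
    size_x = property_constant(8, "px"), size_y = property_constant(8, "px")))
  quiet <- scene_spec("s", 0.5, "p")
  res <- run_scene(quiet, list(stim), display = d, render = FALSE)
  expect_identical(res$frames_rendered, 30L)
  expect_true(is.na(res$response_time))

  answered <- scene_spec("s", 0.5, "p", response = response_spec())
  scripted <- scripted_responder("left", frames = 12L)
  res2 <- run_scene(answered, list(stim), responder = scripted, display = d,
                    render = FALSE, correct_side = "right")
  expect_equal(res2$response_time, 12 / 60)
  expect_identical(res2$frames_rendered, 13L)
  expect_identical(res2$response_value, -1)
  expect_false(res2$correct)
})

test_that("preview frames equal the frames captured during a scene run", {
  test <- tiny_test()
  sc <- test$sections[[1]]$scenes[[1]]
  res <- run_scene(sc, test$stimuli, display = test$settings$display,
                   seed = 42, capture = TRUE)
  for (k in c(0L, 3L, 5L)) {
    pv <- preview_frame(test, "scene1", k, seed = 42)
    expect_identical(pv, res$frames[[k + 1L]])
  }
  expect_error(preview_frame(test, "scene1", 99, seed = 42), "out of range")
  expect_error(preview_frame(test, "nope", 0), "no scene")
})

test_that("dropped frames are exactly those strictly over budget", {
  # a frame exactly on budget (1000/60 ms) is not dropped; strictly over is
  rep60 <- timing_report(c(5, 12, 20, 1000 / 60, 3), 60)
  expect_identical(rep60$dropped_frames$frame, 3L)
  expect_identical(rep60$dropped_frames$duration_ms, 20)
  expect_equal(rep60$percent_dropped, 100 / 5)
  none <- timing_report(rep(8, 10), 120)
  expect_identical(nrow(none$dropped_frames), 0L)
  expect_identical(none$percent_dropped, 0)
  expect_identical(none$frame_budget_ms, 8.33)
  expect_error(timing_report(c(-1, 2), 60), ">= 0")
})

test_that("the results bundle writes the documented CSV and TXT shapes", {
  test <- tutorial_test()
  run <- run_test(test, observer_responder(tutorial_observer()), seed = 4)
  out <- file.path(tempdir(), "bundle")
  paths <- write_results(run, out)
  expect_true(all(file.exists(paths)))

  tab <- utils::read.csv(paths[["csv"]])
  expect_identical(nrow(tab), nrow(run$trials))
  expect_identical(names(tab), names(run$trials))
  expect_equal(tab$scene2_object1_gratingRotation,
               run$trials$scene2_object1_gratingRotation)

  txt <- readLines(paths[["txt"]])
  expect_true(any(grepl("^audio rate: 44100$", txt)))
  expect_true(any(grepl("^screen resolution: 800x600$", txt)))
  expect_true(any(grepl("^frame rate: 60$", txt)))
  expect_true(file.exists(paths[["json"]]))
  unlink(out, recursive = TRUE)
})

test_that("adaptive sections run a live staircase to its stop rule", {
  cfg <- staircase_config(1, 2, step_up = 0.005, step_down = 0.005,
                          start_value = 0.03, n_reversals_stop = 6,
                          min_value = 0, max_value = 0.06)
  grating <- stimulus_spec("g1", "grating", "rectangle", list(
    size_x = property_constant(20, "px"), size_y = property_constant(20, "px"),
    spatial_frequency = property_constant(0.1, "px"),
    gratingRotation = property_variable("scene1_object1_gratingRotation",
                                        "rad")))
  scene <- scene_spec("scene1", list(value = 3, unit = "frames"), "g1",
                      response = response_spec())
  sec <- section_spec("s1", list(scene), 1L,
                      list(variable_binding("scene1_object1_gratingRotation",
                                            NULL, "adaptive", cfg)))
  test <- stim_test("adaptive",
                    settings = list(display = display_profile(64, 64, 10),
                                    rng_seed = 5L),
                    stimuli = list(grating), sections = list(sec))
  expect_identical(nrow(validate_test(test)), 0L)
  run <- run_test(test, observer_responder(tutorial_observer()), seed = 5)
  expect_gt(nrow(run$trials), 6L)
  vals <- run$trials$scene1_object1_gratingRotation
  expect_true(all(vals >= 0 & vals <= 0.06))
  # same seed reproduces the whole adaptive track
  run2 <- run_test(test, observer_responder(tutorial_observer()), seed = 5)
  expect_identical(run$trials, run2$trials)
})

test_that("running the tutorial against a known observer recovers its threshold", {
  test <- tutorial_test()
  obs <- tutorial_observer()
  run <- run_test(test, observer_responder(obs), seed = 2)
  fit <- fit_psychometric(abs(run$trials$scene2_object1_gratingRotation),
                          run$trials$correct,
                          guess_rate = 0.5, lapse_rate = 0.02)
  expect_lt(abs(fit$threshold - obs$threshold) / obs$threshold, 0.5)
})
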