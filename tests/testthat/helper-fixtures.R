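# Shared fixtures, built in code.

# display with pixels_per_cm 10 and viewing distance 1 radian-unit
# (57.2957795 cm), so 1 deg is very nearly 10 px
unit_display <- function(refresh = 60) {
  display_profile(width_px = 100, height_px = 100, pixels_per_cm = 10,
                  refresh_rate = refresh, max_luminance = 500,
                  viewing_distance = 57.2957795, model_name = "unit")
}

tutorial_path <- function() {
  system.file("extdata", "tutorial.stimulitest", package = "stimkit")
}

tutorial_test <- function() read_test(tutorial_path())

tutorial_observer <- function() {
  psychometric_observer(threshold = 0.015, slope = 150, guess_rate = 0.5,
                        lapse_rate = 0.02, form = "logistic")
}

# a deliberately tiny single-scene test, fast to run and render
tiny_test <- function(repetitions = 1L, with_variable = FALSE) {
  props <- list(
    size_x = property_constant(20, "px"),
    size_y = property_constant(20, "px"),
    spatial_frequency = property_constant(0.1, "px"),
    mean_luminance = property_constant(0.5),
    contrast = property_constant(0.8))
  if (with_variable)
    props$gratingRotation <- property_variable("scene1_object1_gratingRotation",
                                               "rad")
  grating <- stimulus_spec("g1", "grating", "rectangle", props)
  scene <- scene_spec("scene1", 0.1, "g1",
                      response = if (with_variable) response_spec() else NULL)
  vars <- if (with_variable)
    list(variable_binding("scene1_object1_gratingRotation", "vals",
                          "all_values_random_order"))
  else list()
  lists <- if (with_variable)
    list(numeric_list("vals", c(-0.1, 0.1))) else list()
  stim_test("tiny",
            settings = list(display = display_profile(64, 64, 10, 60, 500, 57.3,
                                                      "tiny"),
                            rng_seed = 7L),
            stimuli = list(grating),
            sections = list(section_spec("s1", list(scene), repetitions,
                                         vars)),
            lists = lists, first_section = "s1")
}
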