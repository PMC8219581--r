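Package: stimkit
Title: Headless Engine for Declarative Psychophysical Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable engine for visual and auditory psychophysics.
    Tests are described declaratively (sections of scenes of stimuli, with
    numeric lists and per-trial variable bindings) in a plain JSON format,
    validated, and executed headlessly. Visual stimuli (patches, gradients,
    gratings and Gabors, rectangular and radial checkerboards, random-dot
    kinematograms, text, images) are synthesized procedurally frame by
    frame in units of pixels, centimeters, inches or degrees of visual
    angle; auditory stimuli (pure tones, white noise) are synthesized
    sample by sample at 44.1 kHz. Trials are sequenced by the method of
    constant stimuli or transformed up-down staircases, responses come
    from simulated psychometric observers or scripted replays, and results
    are written as a settings report plus a trial-wise CSV table. Includes
    noise-bit contrast dithering, a frame-budget timing model with
    dropped-frame accounting, maximum-likelihood psychometric fitting, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
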