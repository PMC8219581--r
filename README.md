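# stimkit

A headless, scriptable engine for visual and auditory psychophysics in R.

Psychophysical experiments — orientation discrimination, contrast
sensitivity, motion coherence, tone detection — are usually run by
presentation software on a device with a screen and a response surface.
`stimkit` implements the other 95% of such a system as a library: tests
are *declared* in a plain JSON format (a test is a collection of
sections; a section is a sequence of scenes; a scene presents stimuli
and may collect a response), stimuli are synthesized procedurally —
visual templates frame by frame, auditory templates sample by sample at
44.1 kHz — trials are sequenced by the method of constant stimuli or by
adaptive staircases, and results come out as a settings report plus a
trial-wise CSV. A simulated psychometric observer (or a scripted replay)
stands in for the touchscreen, which makes whole experiments runnable,
testable and exactly reproducible on a desk with no hardware.

It is aimed at researchers who want to prototype and pilot an experiment
design in silico — checking the trial arithmetic, the stimulus content,
the staircase dynamics and the analyzability of the output — and at
anyone who needs a reference implementation of the standard primitives.

## What is inside

**Units and geometry.** Sizes convert between px, cm, inch and degrees
of visual angle through a display profile (resolution, px/cm, refresh
rate, maximum luminance, viewing distance). Degrees use the exact chord
formula `s = 2 d tan(θ/2) · ppcm`, not the small-angle approximation.
Time converts between seconds and frames (`16.67` ms frame budget at 60
Hz, `8.33` ms at 120 Hz); luminance fractions convert to cd/m² through
the device's maximum luminance.

**Visual synthesis.** Patches, linear gradients, gratings and Gabors
`L = m(1 + c·G_env·G_mod · cos(2π f (x cosθ + y sinθ) + φ))`,
rectangular and radial checkerboards, random-dot kinematograms (linear,
rotational and expansive flow with Newsome-style coherence), text via a
built-in bitmap font, and PNG images; rectangle/ellipse/cross aperture
masks; additive uniform pixel noise; and noise-bit contrast dithering —
per-pixel, per-frame stochastic rounding between adjacent 8-bit levels
so the *expected* luminance equals the target exactly, making contrast
quasi-continuous on a discrete panel. Scenes composite alpha-over into
H×W×3 frame buffers exportable as PNG.

**Audio synthesis.** Pure tones (linear on/off ramps) and uniform white
noise at 44.1 kHz; scene mixing with sample-accurate onsets, a signed
audiovisual-offset correction, hard clipping; 16-bit mono WAV I/O.

**Procedures.** Constant-stimuli expansion (`all values in random
order` = independent permutation blocks), transformed up-down
staircases (1-up/1-down → 50%, 1-up/2-down → 70.7%, 1-up/3-down →
79.4% convergence points) with reversal-mean threshold estimates,
simulated psychometric observers, and a maximum-likelihood psychometric
fit (`fit_psychometric`, a classed model object with `coef`/`predict`).

**Runner + CLI.** `run_test()` executes a test deterministically from a
seed, accounts every frame against the frame budget (dropped iff
compute time strictly exceeds `1000/Hz` ms) and writes `results.csv`,
`settings.txt` and `timing.json`. The same engine is scriptable from a
shell: `stimkit validate|preview|render|run TEST.stimulitest`.

## Worked example

The packaged tutorial test measures orientation discrimination: each
trial shows a fixation cross (0.5 s), then a Gabor rotated by one of 7
angles from −0.03 to 0.03 rad (selected in random permutation blocks,
20 repetitions), and collects a left/right response.

```r
library(stimkit)

test <- read_test(system.file("extdata", "tutorial.stimulitest",
                              package = "stimkit"))
test
#> <stim_test> 'orientation-discrimination-tutorial'
#>   2 stimuli, 1 section(s), 1 list(s); first section 'section1'
#>   display: generic-tablet (800x600 @ 60 Hz), audio 44100 Hz

obs <- psychometric_observer(threshold = 0.015, slope = 150,
                             guess_rate = 0.5, lapse_rate = 0.02)
run <- run_test(test, observer_responder(obs), seed = 1)
run
#> <stim_run> 'orientation-discrimination-tutorial': 140 trials
#>   12600 frames, 0 dropped (0.00%)
#>   proportion correct: 0.721

fit <- fit_psychometric(abs(run$trials$scene2_object1_gratingRotation),
                        run$trials$correct,
                        guess_rate = 0.5, lapse_rate = 0.02)
fit
#> <psychometric_fit> logistic, 140 trials
#>   threshold 0.019548, slope 174.87 (guess 0.5, lapse 0.02 fixed)
#>   log-likelihood -75.058
```

The run produced the full 7×20 = 140-trial design (each orientation
exactly 20 times), the simulated observer answered 72% of trials
correctly, and fitting the resulting data recovers a threshold of
0.0195 rad against the generating observer's 0.015 rad — within the
sampling error of a 140-trial session. `write_results(run, "out/")`
writes the CSV/TXT/JSON bundle; `preview_frame(test, "scene2", 0,
bindings = list(scene2_object1_gratingRotation = 0.03))` returns any
single frame for inspection.

From a shell:

```sh
Rscript inst/cli/stimkit validate inst/extdata/tutorial.stimulitest
Rscript inst/cli/stimkit run inst/extdata/tutorial.stimulitest \
    --seed 1 --observer inst/extdata/observer_example.json --out out/
```

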