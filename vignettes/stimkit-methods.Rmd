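---
title: "stimkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimkit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimkit)
```

`stimkit` executes declaratively specified psychophysical tests without
hardware: stimuli are synthesized numerically, the display and the
observer are models, and every run is a deterministic function of the
test description and a seed. This vignette records the models behind
each component, the parameters that matter, and the choices we made
where the design was genuinely open.

## The test hierarchy

A *test* is a collection of *sections*; a section is a sequence of
*scenes* presented `repetitions` times (one presentation of the
sequence = one trial); a scene presents *stimuli* simultaneously and
may collect one response. *Numeric lists* bound to stimulus properties
via *variable bindings* make properties vary across trials. This
hierarchy is stored as plain JSON (`.stimulitest`/`.json`), with all
cross-references by name and a `schema_version` field; the format is
deliberately editable by hand, and `validate_test()` checks every
structural invariant (unique names, resolvable references, legal
property names per stimulus type, positive durations and repetition
counts) before anything runs.

Two defaults fill gaps the hierarchy leaves open. Section chaining is
linear: `next_section` defaults to the following section in file order
and `END` after the last, because conditional branching (e.g. on
accuracy) is not part of the model. Variable-binding targets use
1-based positional paths (`scene2_object1_gratingRotation`), matching
the naming convention users see when a property is promoted to a
variable.

## Units and display geometry

A `display_profile` carries `width_px`, `height_px`, `pixels_per_cm`,
`refresh_rate` (Hz), `max_luminance` (cd/m²) and `viewing_distance`
(cm). Degrees of visual angle convert by the exact chord formula

$$ s_{px} = 2\,d\,\tan(\theta/2)\cdot \text{ppcm}, $$

not the small-angle approximation: the two agree to well under 0.1% for
θ < 5°, but the chord stays correct at large eccentricities, and its
inverse `px_to_deg` is exact, so the pair are mutual inverses to 1e−9
relative error over (0, 60]°. Seconds convert to frames by rounding to
the nearest frame (ties away from zero); of the defensible rounding
rules this one minimizes the absolute error between requested and
realized duration, and it reproduces exact frame counts for durations
on the frame grid. The frame budget is `1000/Hz` ms, reported rounded
to two decimals (16.67 ms at 60 Hz, 8.33 ms at 120 Hz).

The shipped device table (`inst/extdata/display_profiles.json`) holds a
few example profiles and is meant to be edited: nominal panel luminance
varies across series and with age, so the table is a convenience, not a
calibration. Gamma/EOTF modeling is out of scope; pixel values are
linear luminance fractions throughout.

## Visual synthesis

Coordinates put the origin at the screen (or patch) center, +x right,
+y up, angles counterclockwise from +x in radians; positions are center
coordinates, and rasters are sampled at pixel centers.

**Gratings.** The carrier-envelope model is
$L = m\,(1 + c_\text{eff}\cos(2\pi f(x\cos\theta + y\sin\theta)+\varphi))$
with $c_\text{eff} = c \cdot G_\text{env} \cdot G_\text{mod}$, where
$G_\text{env}$ is a unit-peak isotropic Gaussian of width
`envelope_sigma` (a Gabor when present) and $G_\text{mod}$ a second
unit-peak Gaussian implementing carrier-contrast modulation. The
modulation window's functional form was an open choice; we use a
Gaussian for symmetry with the envelope. `contrast` is Michelson
contrast about the mean for periodic stimuli; for uniform patches it
scales the deviation from mid-gray. Spatial frequency is written in
cycles/degree in test files (the field's convention) and converted to
cycles/px through the display profile. At θ = 0 the carrier varies
along x — a vertical grating.

**Checkerboards.** Rectangular parity is
`(⌊x/w⌋ + ⌊y/h⌋) mod 2`; radial parity is
`(sector(atan2(y,x)) + ⌊r/ring⌋) mod 2` with `n_sectors` equal angular
sectors. Parity selects between the two check colors.

**Random dots.** Coherence is membership-based: each dot is a signal or
noise dot for its whole lifetime, drawn with probability `coherence` at
birth, so the expected signal fraction equals the coherence. Signal
dots move per kind — linear translation; *radial* = rotation about the
aperture center through `speed/r` radians (constant arc length, i.e.
tangential motion); *expansive* = radial displacement by `speed` along
the outward ray (negative contracts). Noise dots move at the same speed
in a direction drawn independently uniform on every frame. Dots that
expire (`dot_lifetime` frames) or exit the circular aperture are
redrawn uniformly in the aperture with age 0 and fresh membership, so
the dot count is invariant.

**Noise filter.** The general "noise" property is implemented as
additive zero-mean uniform luminance noise of half-range
`noise_filter`, one draw per pixel applied to all three channels, then
clipped to [0,1]. Additive uniform noise is the simplest semantics
consistent with a per-pixel noise mask; multiplicative or
frequency-filtered variants would be extensions.

**Noise-bit dithering.** `quantize_noise_bit` stochastically rounds a
real value in [0,1] to one of its two adjacent levels among the
$2^{8}$ panel levels, choosing the upper level with probability equal
to the fractional position between them, independently per pixel and
frame. The expected displayed level then equals the target value
*exactly*, which is what makes contrast quasi-continuous on an 8-bit
panel; the cost is spatiotemporal noise with per-pixel variance at most
a quarter of a level squared. Bit depth defaults to 8 (typical panel
depth).

**Text and images.** Text renders through a built-in 5×7 bitmap font
scaled by `text_scale` — no system font dependency, at the price of
cosmetic glyph fidelity, which is explicitly not a contract of the
engine. Images are PNG only and resampled nearest-neighbor.

**Compositing.** Scenes composite patches alpha-over, in draw order,
onto a background-filled buffer, clipping at screen edges. Rendering is
a pure function of (specification, resolved properties, frame index,
seed): all stochastic elements (noise, dithering, dot updates) draw
from locally scoped RNG streams derived from the seed, never from the
session RNG.

## Audio synthesis

Buffers are mono (channels are never part of the model here) at a
default 44.1 kHz. Tones are `a·env(i)·sin(2πfi/r)` with a linear on/off
ramp, default 5 ms, to avoid onset clicks — with `ramp = 0` the
waveform is the bare sinusoid. Requested durations are realized as
`round(duration·rate)` samples, so a 100-ms tone is 4410 samples at
44.1 kHz with zero variance across requests — the artifact-level
counterpart of measuring realized tone durations on an oscilloscope.
Frequencies at or above Nyquist are refused. Auditory noise is
i.i.d. uniform in `[-a, a]`. Scene mixing places each event at
`round((onset + av_offset_ms/1000)·rate)` samples; the signed
`av_offset_ms` models the device-specific audiovisual onset asynchrony
a user would measure and enter to correct it. Overflow hard-clips with
a warning; onsets pushed before zero truncate with a warning. WAV I/O
is 16-bit PCM mono (round trip within one quantization step).

## Trial sequencing and the simulated observer

**Constant stimuli.** `all values in random order` with R repetitions
is interpreted as R independent permutation blocks of the full list —
n·R trials with each value occurring exactly R times and exactly once
per block. (The alternative reading, R as a cap on total trials, does
not reproduce the canonical n-values × R-repetitions design.) `fixed`
repeats the list's first value; `random_with_replacement` draws
independently each trial.

**Staircases.** The adaptive family is the transformed up-down rules
(1-up/n-down with configurable asymmetric steps, clamping bounds and a
reversal-count stop), the most common procedures in the adaptive
literature; Bayesian procedures (QUEST/Psi) are deliberate extension
points, not shipped. A reversal is recorded whenever the step direction
changes, at the pre-step value; `staircase_estimate` averages the last
k reversals. The 1-up/2-down rule converges to the level answered
correctly with probability $2^{-1/2} \approx 70.7\%$, 1-up/1-down to
50%.

**Observer.** The simulated observer answers correctly with probability
$P = \gamma + (1-\gamma-\lambda)\,F(|x|;\,\alpha,\beta)$, F a logistic
or cumulative-Gaussian sigmoid with $F(\alpha) = 0.5$; γ is the guess
rate (0.5 for two-alternative tasks), λ the lapse rate. For left/right
tasks the correct side is derived from the sign of the trial's varying
property (positive → right, as in clockwise/counterclockwise
discrimination; zero → a seeded coin flip). The observer responds at a
configurable latency, by default the last frame of the response scene.

What this observer emulates is the *decision* process: stationary
sensitivity, independence across trials, symmetric left/right mapping.
It does not emulate reaction-time distributions, sequential effects,
learning or fatigue, spatial tap scatter, or the touch-sampling
granularity of real hardware — so passing end-to-end tests demonstrates
the engine's arithmetic and plumbing, not human performance.

**Fitting.** `fit_psychometric` maximizes the binomial likelihood of
the same two-parameter model (guess and lapse fixed; lapse default 0.01
to keep the likelihood bounded under occasional errors at high values)
over threshold and log-slope by Nelder-Mead from a deterministic start
(median stimulus value; slope ~4/range), so refits are identical.
All-correct or all-wrong data are flagged as boundary cases: a warning
is raised and the threshold is reported as the midpoint of the extreme
stimulus values.

## The runner and the timing model

Execution is offline: the runner never sleeps and never syncs to a real
display. It still measures the wall-clock synthesis time of every frame
and applies the frame-budget law — a frame is dropped iff its compute
time *strictly* exceeds `1000/Hz` ms (a frame finishing exactly on
budget makes the refresh) — producing a per-run dropped-frame report
with each dropped frame's duration. This keeps the accounting model of
a real-time engine while making desk-scale runs deterministic.

By default `run_test` executes trial logic (property resolution,
responder sampling, per-frame timing) without synthesizing pixels;
`render = TRUE` synthesizes every frame, and `preview_frame()`
reproduces bit-identically the frame a captured scene run would yield
at the same seed — frame-to-frame state such as dot fields is replayed
from the scene start. Responses are sampled once per frame, so response
times have one-frame resolution by construction.

Outputs follow the two-file convention: `settings.txt` with `key:
value` lines (audio rate, screen resolution, frame rate, device model,
seed, ...) and `results.csv` with one row per trial and one column per
bound variable plus the response columns; `timing.json` carries the
dropped-frame report. Given the same test file and seed, the CSV and
TXT are byte-identical across runs.

## Problem sizes and what the tests compute

The test suite and the acceptance script work at desk scale, chosen so
the whole suite runs in seconds while keeping Monte-Carlo bounds sharp:
synthesis oracles on 64×64 and 100×100 grids against naive double-loop
references (agreement to 1e−12); noise statistics on 10⁵–10⁶ draws with
3σ CLT bounds; staircase convergence as the median of 200 seeded runs
against the analytic 70.7%/50% points (within 2 step sizes); threshold
recovery over the packaged 7×20 orientation design across 100 seeded
replicates (mean bias under 20%). The tutorial fixture itself uses a
modest 800×600 profile; nothing in the engine depends on that size.

## Known limitations

- No gamma/EOTF or color management; values are linear fractions.
- PNG images only; no video stimuli.
- Mono audio; no hardware latency measurement (the AV offset is a
  user-supplied correction, not a measurement).
- Glyph metrics of the bitmap font are cosmetic.
- No import compatibility is claimed with test files produced by other
  software; the JSON dialect is this package's own.
- The observer model is stationary and memoryless by design.
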