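---
title: "Detecting carbachol-induced oscillation bands in MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting carbachol-induced oscillation bands in MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meabands)
library(dplyr)
```

## The measurement and the question

Organotypic hippocampal slice cultures sit on a planar microelectrode array
(MEA) with 60 electrodes. A brief pulse of the cholinergic agonist
carbachol induces network oscillations; each trial records 30 s of
baseline, the 1 s application, and about 30 s of response, for 60 s in
total. Six trials are recorded per culture; the first is treated as
carbachol-naive and discarded, leaving five for analysis. Each electrode
is assigned to a hippocampal subregion (DG, CA3 or CA1) from photographs
of the culture on the array.

The scientific questions this package serves are binary and comparative:
in which of the four canonical frequency bands — delta (1–4 Hz), theta
(4–10 Hz), beta (10–30 Hz), gamma (30–100 Hz) — does a culture oscillate
after carbachol, and how does the probability of oscillating depend on
days in vitro (DIV), genotype, and hippocampal area? A follow-up question
asks whether the peak frequency and relative peak power of the detected
oscillations differ between conditions.

`meabands` implements the full chain: a synthetic-recording generator
(so every stage can be tested against ground truth), preprocessing,
DPSS-multitaper spectral estimation, prominence-based band detection, and
binomial occurrence modelling with AIC model selection.

## The analysis pipeline

### Preprocessing

Raw 20 kHz recordings are decimated to 1 kHz and high-pass filtered at
1 Hz with a fourth-order Butterworth filter.

* **Decimation.** The anti-alias low-pass is a zero-phase
  frequency-domain filter: unit gain up to 0.40 × target rate (400 Hz),
  raised-cosine rolloff reaching zero at 0.45 × target rate (450 Hz),
  applied under reflect padding, followed by taking every 20th sample.
  A frequency-domain filter was chosen over a time-domain FIR because the
  transition band required here would need a filter of several hundred
  taps per channel on 1.2-million-sample channels; the FFT filter is
  exact, fast, zero-phase and deterministic. The stopband edge at
  0.45 × fs leaves a guard band below the new Nyquist frequency.
* **High-pass.** The filter is Butterworth of order 4 with 1 Hz cutoff.
  By default it is applied with zero net phase shift and a squared
  magnitude response — the transfer function of a forward–backward pass —
  realised exactly by multiplying each channel's spectrum by
  `|H(e^{iω})|²` under reflect padding (ten filter time constants at
  each end). Zero-phase filtering avoids latency distortion of the
  onset-aligned analysis windows; a causal single pass is available via
  `preprocess_config(zero_phase = FALSE)` since it is not documented
  which convention the original MATLAB analysis used. The closed-form
  magnitude response is exposed as `butterworth_highpass_response()` and
  the implementation is tested against it.

### Multitaper spectral estimation

Time–frequency analysis is a short-time Fourier transform with DPSS
(Slepian) multitapers: a 1 s window shifted by 100 ms across the trial,
frequencies 1–500 Hz on a 1 Hz grid. "Smoothing over ±2 Hz" is read as
the multitaper half-bandwidth W = 2 Hz, so the time–bandwidth product is
NW = 2 and the conventional K = 2NW − 1 = 3 tapers are averaged; the
taper count is configurable. The tapers are computed from the standard
symmetric-tridiagonal eigenproblem, cached, and checked for orthonormality
in the tests.

The post-stimulus spectrum of a channel is the mean over all windows whose
start time is at or after the onset (30 s), i.e. 291 of the 591 windows of
a 60 s trial; a median is selectable. Because only those windows enter the
analysis, the pipeline computes them directly from the post-onset segment
— a pure optimisation whose equality with the full-spectrogram path is
asserted by a test.

Each per-channel spectrum then passes through three further stages, in an
enforced order (each spectrum carries a `stage` field and each operation
refuses any other input stage, pinning down the order rather than hiding
it):

1. **1/f correction** — multiply each value by its frequency, flattening
   the 1/f background of field potentials.
2. **Line-harmonic excision** — around every harmonic of 50 Hz inside the
   range (50, 100, …, 500 Hz), power within ±3 Hz is cut out and the gap
   bridged by linear interpolation between the boundary grid values; at
   the upper grid edge the interval is clipped and the remaining anchor
   extended flat.
3. **Normalization** — each channel's spectrum is divided by its own sum,
   making channels with different absolute power comparable. An all-zero
   channel cannot be normalized; it is flagged inactive and excluded from
   detection instead of raising an error.

Trials of one culture are averaged after per-trial normalization (the
default), which makes trials with different overall response power
commensurate; averaging the corrected spectra first and normalizing once
at the end is available via `average = "raw"`. The naive first trial is
always excluded.

### Band detection

The detector works on the normalized spectrum of each channel:

* All strict local maxima are found; flat-topped plateaus count once, at
  their centre grid point. Each peak's **prominence** is computed by the
  horizontal-line rule: extend a line left and right from the maximum
  until the signal rises above the peak height or the end of the spectrum
  is reached, take the minimum of each interval, and subtract the higher
  of the two minima from the peak height. This primitive is implemented
  from scratch and verified, exactly, against an independent brute-force
  implementation on 10⁴ random vectors.
* Within a band's search range, each channel contributes its
  highest-prominence peak (prominence, not height, because the threshold
  acts on prominence). Channels whose best peak reaches **0.001
  normalized units** are *active*; the band is *present* if at least one
  channel is active.
* The band's **mode frequency** is the mode of the active channels' peak
  frequencies, ties resolved toward the lower frequency (a deterministic
  rule; the original analysis does not state one).
* The four canonical ranges are scanned directly, replacing the original
  study's manual, blinded selection of candidate frequency ranges. The
  manual step only located ranges that were then categorized into the
  same four bands; scanning the bands themselves makes the procedure
  reproducible. Band edges are half-open — 4 Hz is theta, 10 Hz beta,
  30 Hz gamma — so the four ranges partition 1–100 Hz; 100 Hz closes
  gamma.
* **Relative peak power** divides the power at each active channel's peak
  frequency by the mean power in the 200–250 Hz reference band (51 grid
  points, endpoints inclusive), controlling for broadband power changes.
  It is evaluated on the 1/f-corrected (pre-normalization) spectrum so it
  remains a genuine power contrast; the band-level summary is the mean
  over active channels, and per-channel values are also returned since it
  is not documented whether the original analysis used the mode-frequency
  channel or an average.

### Occurrence statistics

Detection per culture × area × band yields a binary occurrence table.
Modelling follows two passes, as in the underlying study design: first
per-area rows with genotype, DIV and area as candidate predictors; then —
since area is not retained — per-culture rows where a culture counts as
oscillating in a band if **any** of its areas was active.

Occurrence is modelled by binomial logistic regression (`stats::glm`).
DIV enters as a categorical factor by default (matching per-DIV
statements of effect), with a numeric coding available. The candidate set
for model selection is every model from intercept-only to the full
factorial that respects marginality (an interaction only ever appears
together with all its lower-order terms) — 19 models for three factors,
5 for two. Models are ranked by AIC = 2k − 2 ln L (the identity is
asserted in tests); ties prefer the smaller model; the winner is reported
together with a likelihood-ratio test against the null model.

Perfect or quasi-complete separation — a real risk at 13 cultures per
cell — is detected (runaway log-odds or fitted probabilities at 0/1) and
flagged `converged = FALSE` rather than silently returned; a Firth-style
penalized fit (score adjusted by hat values, damped Newton steps) is
available to keep estimates finite.

Peak frequency and relative peak power are compared across genotype × DIV
with fixed-effects two-way ANOVA using Type II sums of squares
(`car::Anova`), appropriate for the unbalanced cell counts that arise
when only cultures expressing a band contribute. Significance is flagged
at a family-wise α = 0.0125 — 0.05 split across the family of four
band-wise tests. If any design cell is empty the interaction is dropped
with a warning; degenerate responses (zero residual variance) yield
undefined statistics flagged non-significant rather than an error.

## The synthetic-recording generator

No recordings were published with the study this pipeline re-implements,
so the generator is a first-class module: it emulates exactly the
statistical structure the analysis assumes, and every downstream claim is
tested against its ground truth.

A generated trial is the sum of:

* **1/f (pink) background**, synthesized in the frequency domain with
  amplitude ∝ 1/√f for f ≥ 1 Hz (zero below 1 Hz and at DC) and uniform
  random phases, scaled to an RMS of 10 µV per channel. The periodogram
  slope of −1 over 2–400 Hz is a tested invariant.
* **White noise** at 2 µV SD, the electrode/amplifier noise floor.
* **Line hum** at 50 Hz with harmonics at 100 and 150 Hz, amplitudes 5,
  2.5 and 1.25 µV, one shared phase per harmonic across channels (one
  physical source) — placed so the excision stage is exercised on real
  content, not just empty bins.
* **Band oscillations** for each band drawn present: by default a
  sinusoid at the band's centre frequency with a per-channel random
  phase, amplitude 15 µV, zero before the stimulus onset and ramping
  linearly over 0.5 s after it; band-pass-filtered Gaussian noise is
  selectable (`osc_waveform = "noise"`). Both waveforms put a single peak
  in the band, which is the only property the detector uses. The
  oscillation is carried by a random half of the channels in the band's
  areas (all three areas by default, matching the observation that no
  area dominated), and the active-channel layout is drawn **once per
  culture** — the electrodes sit on the same tissue in every trial.

Default amplitudes were set once, from the physiology (tens of µV
oscillations over a ~10 µV 1/f floor) and the requirement that a present
band is unambiguous to an independent band-power check; they were not
revisited afterwards.

Band centres are 2, 7, 20 and 40 Hz. Three of these are the values the
field reports for carbachol-induced activity (delta peaking at 3 Hz, beta
near 20 Hz, gamma near 40 Hz). The delta **generator** centre is 2 Hz
rather than 3 Hz for a pipeline-aware reason worth recording: the ±2 Hz
multitaper smoothing spreads a narrowband peak into a ~5-bin-wide plateau,
and the subsequent multiply-by-frequency correction tilts that plateau
upward, moving the reported maximum about one 1 Hz grid step up. A 2 Hz
source therefore *reports* as a 3 Hz delta peak — the canonical value —
while a 3 Hz source would report at 4 Hz and be categorized as theta.
This bias is a property of the correct, specified pipeline, not a defect
of the implementation; it is invisible for bands whose range is wide
relative to one grid step and only matters at the narrow delta range.

**Occurrence model.** Per-culture presence of each band is Bernoulli with
probability logistic(intercept + DIV offset + genotype offset). Defaults:
delta 49%, theta 22% and beta 91% at every DIV; gamma 27% at DIV 7, 62%
at DIV 13, 65% at DIV 26; no genotype effect. Presence is a per-culture
property shared by all trials — the study design averages trials within a
culture precisely because expression is treated as stable within a
recording session; inter-trial variability of expression is not reported
anywhere we could anchor it, so it is deliberately not modelled.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no biophysical dynamics (the "oscillation" is a
stationary narrowband process, not an emergent network rhythm); no
spatial correlation between electrodes beyond the shared hum and the
shared band membership; no carbachol application artifact (explicitly not
part of the analyzed data in the original design); no drift,
electrode-quality differences, or artifacts that real MEA recordings
contain. Detection performance on real recordings will be bounded by
those factors, not by the ones tested here.

## Numerical choices and degenerate inputs

* Frequency grid: the 1 s window gives exactly 1 Hz spacing; excision
  anchors are the grid points at exactly ±3 Hz around each harmonic.
* Window count: `floor((duration − window)/step) + 1` windows, starts at
  0, 0.1, … s — 591 for a 60 s trial; the convention is asserted, since
  the original toolbox's alignment convention is not documented.
* Stage order: 1/f correction and excision are applied to the
  time-averaged post-stimulus spectrum rather than per window — the
  operations are linear/affine in power, so the results are identical and
  the averaged route is ~300× cheaper.
* All-zero channels are flagged inactive, not errors; all-naive trial
  sets, empty search ranges, non-integer decimation factors, and
  out-of-range cutoffs are explicit errors.
* Determinism: every stochastic step runs under an explicit seed; a
  fixed (config, seed) pair reproduces recordings bit-exactly and
  pipeline outputs byte-identically. RNG state of the caller is restored.
* Mode ties → lowest frequency; equal-AIC models → fewest parameters;
  plateau peaks → centre grid point (lower-middle for even plateaus).

## Simulation sizes

The test suite and the acceptance script exercise the pipeline at the
study's per-recording scale — 60 channels, 60 s trials, 30 s onset — and
choose cohort sizes for statistical power: 204 cultures (34 per
genotype × DIV cell) for detection recovery with one analyzed trial per
culture (the single-trial condition is statistically harder than the
five-trial average used in the study, since averaging suppresses noise
prominences); 200 cultures per cell and 100 replicate cohorts for
occurrence-model recovery, where recordings are not needed and presence
is drawn directly from the occurrence model; 100 seeded 60 s trials for
the tone-in-pink-noise frequency check. Unit tests use smaller geometries
(6–12 channels, 12–24 s) where the property under test does not depend on
scale.

## Known limitations

* The detector reports one mode frequency per band per culture; it does
  not resolve multiple distinct oscillations within one band, nor
  time-resolved (burst) structure — matching the original analysis, which
  categorized at the band level.
* The prominence threshold of 0.001 normalized units is taken as given.
  Its false-positive behaviour depends on the number of windows averaged;
  with a single 30 s post-stimulus average it has a small but non-zero
  per-channel false-positive rate, which the five-trial averaging of the
  study design suppresses further.
* The 1/f-correction bias discussed above shifts reported peak
  frequencies of narrow low-frequency oscillations upward by about one
  grid step; comparisons *between* conditions are unaffected because the
  bias is identical across conditions.
* Firth penalization is a plain hat-value score adjustment without
  profile-likelihood confidence intervals; flagged separation should be
  inspected, not just refitted.
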