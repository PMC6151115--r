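# meabands

Oscillation-band detection and occurrence modelling for multichannel
microelectrode-array (MEA) recordings of organotypic hippocampal slice
cultures.

Brief application of the cholinergic agonist carbachol makes hippocampal
tissue oscillate. Recorded on a 60-electrode MEA, each 60 s trial holds a
30 s baseline, the 1 s application, and the response. The questions are
binary and comparative: in which canonical LFP bands — delta (1–4 Hz),
theta (4–10 Hz), beta (10–30 Hz), gamma (30–100 Hz) — does a culture
oscillate, and how does the probability of oscillating depend on days in
vitro (DIV), genotype and hippocampal area (DG/CA3/CA1)?

`meabands` provides the full analysis chain, plus a synthetic-recording
generator so that every stage can be validated against known ground truth:

* **Preprocessing** — decimation from 20 kHz to 1 kHz behind a zero-phase
  anti-alias low-pass, then a zero-phase order-4 Butterworth high-pass at
  1 Hz.
* **Spectral estimation** — sliding-window (1 s window, 100 ms step) DPSS
  multitaper spectra on a 1 Hz grid over 1–500 Hz with ±2 Hz smoothing
  (NW = 2, K = 3 Slepian tapers); post-stimulus averaging; 1/f correction
  by multiplying power by frequency; excision of ±3 Hz around every 50 Hz
  line harmonic with linear interpolation across the gap; per-channel
  unit-sum normalization.
* **Band detection** — per channel, the highest-prominence spectral peak
  in each band range; channels whose peak prominence reaches 0.001
  normalized units are *active*; a band is *present* when any channel is
  active, its frequency is the mode of active channels' peak frequencies,
  and its peak power is reported relative to the mean power at 200–250 Hz.
  Peak prominence follows the horizontal-line definition (extend left and
  right to the nearest higher point or the spectrum edge; subtract the
  higher of the two interval minima) and is verified exactly against a
  brute-force oracle.
* **Occurrence statistics** — binomial logistic regression of per-culture
  presence on genotype, DIV and area, AIC selection over all
  marginality-respecting candidate models, area collapse by
  any-area-active, separation flagging with optional Firth-style
  penalization, and two-way Type II ANOVA (family-wise α = 0.0125) for
  peak frequency and relative peak power.

Everything is tibble-native: detection results, occurrence tables, model
rankings and ANOVA tables are tibbles; fitted models support
`tidy()`/`glance()`; result objects have `autoplot()` methods.

## Worked example

Simulate one wild-type culture at DIV 13, analyse its trials, and read off
the detected bands:

```r
library(meabands)
library(dplyr)

cfg    <- generator_config(rng_seed = 2024L)   # 60 channels, 60 s trials
truth  <- draw_cohort(cfg, n_cultures_per_cell = 1,
                      divs = 13, genotypes = "WT", seed = 7L)
trials <- generate_culture(cfg, truth, n_trials = 6, trial_indices = 2:3)
det    <- analyze_culture(trials)
det |> filter(area == "all") |>
  select(band, present, n_active, mode_freq, peak_power_rel)
#>    band present n_active mode_freq peak_power_rel
#> 1 delta   FALSE        0        NA             NA
#> 2 theta   FALSE        0        NA             NA
#> 3  beta    TRUE       30        21       41.51033
#> 4 gamma   FALSE        0        NA             NA
```

This culture was drawn with only a beta oscillation present (the
generator's ground truth in `truth`), and the detector recovers exactly
that: 30 of 60 channels active, a 21 Hz mode frequency, and a peak power
about 42× the 200–250 Hz reference level.

Model gamma occurrence across a small cohort (13 cultures per
genotype × DIV cell, presence drawn from the generator's logistic model —
27/62/65% at DIV 7/13/26):

```r
occ <- draw_cohort(cfg, n_cultures_per_cell = 13, seed = 11L) |>
  filter(band == "gamma")
sel <- select_model(occ)
tidy(sel)
#>   formula                           k log_lik   aic converged delta_aic
#> 1 div                               3   -48.0  102. TRUE           0
#> 2 genotype + div                    4   -47.8  104. TRUE           1.76
#> 3 genotype + div + genotype:div     6   -47.4  107. TRUE           4.91
#> 4 1                                 1   -53.8  110. TRUE           7.74
#> 5 genotype                          2   -53.7  111. TRUE           9.53

fitted_occurrence(sel$best)
#>   div   probability
#> 1 7           0.269
#> 2 13          0.692
#> 3 26          0.654
```

AIC selects the DIV-only model; the fitted per-DIV occurrence
probabilities (26.9%, 69.2%, 65.4%) recover the generating curve at this
sample size.

The whole chain — simulate a cohort, analyse every culture, fit and rank
occurrence models, run the ANOVA comparisons, write all tables plus the
resolved configuration and a run log — is one call:

```r
cfg_run <- pipeline_config(cohort = list(n_cultures_per_cell = 4L,
                                         n_trials = 6L),
                           seed = 1L)
res <- run_pipeline(cfg_run, out_dir = "results/run1")
```

Outputs are byte-identical across runs with the same configuration and
seed.

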