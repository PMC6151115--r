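# Synthetic-recording generator: determinism, spectral shape, oscillation
# placement, and the logistic occurrence model.

test_that("all sources silenced yields an all-zero recording", {
  cfg <- tiny_config(pink_noise_amplitude = 0, white_noise_amplitude = 0,
                     hum_harmonic_amplitudes = 0)
  rec <- generate_recording(cfg, tiny_meta(), list())
  expect_true(all(rec$signal == 0))
  expect_equal(dim(rec$signal), c(6L, 12 * 1000))
})

test_that("identical config and seed reproduce the recording bit-exactly", {
  cfg <- tiny_config()
  r1 <- generate_recording(cfg, tiny_meta(), c(gamma = TRUE, delta = TRUE))
  r2 <- generate_recording(cfg, tiny_meta(), c(gamma = TRUE, delta = TRUE))
  expect_identical(r1$signal, r2$signal)
  r3 <- generate_recording(cfg, tiny_meta(), c(gamma = TRUE, delta = TRUE),
                           seed = 999L)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("unknown band names and broken timing are rejected", {
  cfg <- tiny_config()
  expect_error(generate_recording(cfg, tiny_meta(), c(sigma = TRUE)),
               "sigma")
  expect_error(generate_recording(cfg, trial_meta("x"), list()),
               "timing")
  expect_error(generator_config(fs = 1000, duration_s = 1.0005), "integer")
  expect_error(
    generator_config(bands = list(gamma = band_spec(center = 150))),
    "outside"
  )
})

test_that("present bands raise post-onset bandpower only on their channels", {
  # gamma at 40 Hz in half the channels: bandpower(35-45) rises >= 5x after
  # onset exactly there, and nowhere else
  cfg <- generator_config(
    n_channels = 10L, duration_s = 20, onset_s = 10, rng_seed = 7L,
    bands = list(gamma = band_spec(center = 40, amplitude = 15,
                                   fraction = 0.5))
  )
  meta <- trial_meta("c", 2, onset_s = 10, duration_s = 20)
  rec <- generate_recording(cfg, meta, c(gamma = TRUE))
  act <- attr(rec, "active_channels")$gamma
  expect_length(act, 5L)
  n_on <- 10 * 1000
  ratio <- vapply(seq_len(10), function(ch) {
    pre <- oracle_bandpower(rec$signal[ch, 1:n_on], 1000, 35, 45)
    post <- oracle_bandpower(rec$signal[ch, (n_on + 1):(2 * n_on)], 1000, 35, 45)
    post / pre
  }, numeric(1))
  expect_true(all(ratio[act] >= 5))
  expect_true(all(ratio[-act] < 5))
  # background only before the onset: no 35-45 Hz excess pre-stimulus
  expect_lt(max(oracle_bandpower(rec$signal[act[1], 1:n_on], 1000, 35, 45)),
            oracle_bandpower(rec$signal[act[1], (n_on + 1):(2 * n_on)], 1000,
                             35, 45) / 5)
})

test_that("a culture's trials share one active-channel layout", {
  cfg <- tiny_config()
  truth <- draw_cohort(cfg, 1, divs = 13, genotypes = "WT", seed = 21)
  trials <- generate_culture(cfg, truth, n_trials = 3)
  layouts <- lapply(trials, attr, "active_channels")
  expect_identical(layouts[[1]], layouts[[2]])
  expect_identical(layouts[[2]], layouts[[3]])
  expect_true(trials[[1]]$meta$naive)
  expect_false(trials[[2]]$meta$naive)
  # trial subsets reproduce the same recordings
  only2 <- generate_culture(cfg, truth, n_trials = 3, trial_indices = 2)
  expect_identical(only2[[1]]$signal, trials[[2]]$signal)
})

test_that("pure pink noise has log-log periodogram slope about -1", {
  cfg <- generator_config(n_channels = 2L, duration_s = 30, onset_s = 15,
                          white_noise_amplitude = 0,
                          hum_harmonic_amplitudes = 0, rng_seed = 5L)
  rec <- generate_recording(cfg, trial_meta("c", 2, onset_s = 15,
                                            duration_s = 30), list())
  n <- n_samples(rec)
  f <- (seq_len(n) - 1) * 1000 / n
  for (ch in 1:2) {
    p <- Mod(fft(rec$signal[ch, ]))^2 / n
    # average the raw periodogram into 1 Hz bins before fitting
    sel <- f >= 1 & f <= 450
    bins <- round(f[sel])
    pb <- tapply(p[sel], bins, mean)
    fb <- as.numeric(names(pb))
    expect_lt(abs(loglog_slope(fb, as.numeric(pb)) - (-1)), 0.15)
  }
})

test_that("filtered-noise waveform also lands in its band", {
  cfg <- generator_config(
    n_channels = 4L, duration_s = 20, onset_s = 10, rng_seed = 13L,
    osc_waveform = "noise",
    bands = list(beta = band_spec(center = 20, bandwidth = 4,
                                  amplitude = 15, fraction = 1))
  )
  rec <- generate_recording(cfg, trial_meta("c", 2, onset_s = 10,
                                            duration_s = 20), c(beta = TRUE))
  n_on <- 10 * 1000
  post <- oracle_bandpower(rec$signal[1, (n_on + 1):(2 * n_on)], 1000, 16, 24)
  pre <- oracle_bandpower(rec$signal[1, 1:n_on], 1000, 16, 24)
  expect_gt(post / pre, 5)
})

test_that("occurrence model reproduces its configured probabilities", {
  cfg <- generator_config()
  # logistic(0) = 0.5 when everything is zeroed
  cfg0 <- generator_config(occurrence = list(
    gamma = list(intercept = 0, div = c("7" = 0), genotype_ko = 0)
  ))
  expect_equal(occurrence_probability(cfg0, "gamma", "WT", 7), 0.5)
  # study defaults
  expect_equal(occurrence_probability(cfg, "gamma", "WT", 7), 0.27)
  expect_equal(occurrence_probability(cfg, "gamma", "WT", 13), 0.62)
  expect_equal(occurrence_probability(cfg, "gamma", "KO", 26), 0.65)
  expect_equal(occurrence_probability(cfg, "delta", "WT", 13), 0.49)
  expect_equal(occurrence_probability(cfg, "theta", "KO", 7), 0.22)
  expect_equal(occurrence_probability(cfg, "beta", "WT", 26), 0.91)
})

test_that("cohort presence rates match the logistic model within 3 SE", {
  cfg <- generator_config()
  truth <- draw_cohort(cfg, n_cultures_per_cell = 1000, seed = 404)
  rates <- dplyr::summarise(
    dplyr::group_by(truth, genotype, div, band),
    rate = mean(present), n = dplyr::n(), .groups = "drop"
  )
  for (i in seq_len(nrow(rates))) {
    p <- occurrence_probability(cfg, as.character(rates$band[i]),
                                rates$genotype[i], rates$div[i])
    se <- sqrt(p * (1 - p) / rates$n[i])
    expect_lt(abs(rates$rate[i] - p), 3 * se + 1e-12)
  }
  expect_error(draw_cohort(cfg, 1, divs = numeric(0)), "non-empty")
})

test_that("generated presence agrees with direct pre/post bandpower", {
  # presence honesty at default amplitudes, small cohort. The canonical
  # delta range keeps most of the 1/f background, so an active channel's
  # post/pre band-power ratio is ~6 there (far larger in the other bands);
  # noise-only channels sit at 1 +/- ~0.2. A ratio of 2 separates the two.
  cfg <- generator_config(n_channels = 12L, rng_seed = 1L)
  truth <- draw_cohort(cfg, 2, seed = 77)
  br <- band_ranges()
  agree <- 0L; total <- 0L
  for (id in unique(truth$culture_id)) {
    tr <- generate_culture(cfg, truth[truth$culture_id == id, ],
                           n_trials = 2, trial_indices = 2)[[1]]
    n_on <- 30 * 1000
    for (b in seq_len(nrow(br))) {
      hit <- FALSE
      for (ch in seq_len(12)) {
        pre <- oracle_bandpower(tr$signal[ch, 1:n_on], 1000,
                                br$fmin[b], br$fmax[b])
        post <- oracle_bandpower(tr$signal[ch, (n_on + 1):(2 * n_on)], 1000,
                                 br$fmin[b], br$fmax[b])
        if (post / pre >= 2) { hit <- TRUE; break }
      }
      truth_b <- truth$present[truth$culture_id == id &
                                 truth$band == br$band[b]]
      total <- total + 1L
      if (hit == truth_b) agree <- agree + 1L
    }
  }
  expect_gte(agree / total, 0.99)
})
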