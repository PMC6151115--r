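# Multitaper spectral estimation and the staged spectrum pipeline.

test_that("DPSS tapers are orthonormal and match the taper-count rule", {
  tp <- dpss_tapers(1000, 2, 3) # NW = 1 s x 2 Hz, K = 2 NW - 1 = 3
  G <- crossprod(tp)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  # first taper is positive, bell-shaped, concentrated in the window
  expect_true(all(tp[, 1] > 0))
  expect_gt(sum(tp[400:600, 1]^2), 0.5)
})

test_that("window count follows floor((duration - window) / step) + 1", {
  cfg <- generator_config(n_channels = 1L, rng_seed = 3L)
  rec <- generate_recording(cfg, trial_meta("s", 2), list())
  spg <- multitaper_spectrogram(rec)
  expect_equal(dim(spg$power)[2], 591L)
  expect_equal(spg$window_starts[1], 0)
  expect_equal(spg$window_starts[591], 59)
  expect_equal(spg$freqs, 1:500)
  short <- mea_recording(matrix(rnorm(500), 1), 1000, "DG",
                         trial_meta("s", 2, onset_s = 0.2, duration_s = 0.5))
  expect_error(multitaper_spectrogram(short), "shorter")
})

test_that("a 40 Hz tone in white noise peaks at 40 Hz (periodogram oracle)", {
  fs <- 1000
  set.seed(8)
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 40 * t) + rnorm(length(t), sd = sqrt(0.05))
  rec <- mea_recording(matrix(x, 1), fs, "CA3",
                       trial_meta("s", 2, onset_s = 10, duration_s = 20))
  spg <- multitaper_spectrogram(rec)
  avg <- colMeans(spg$power[1, , ])
  expect_lte(abs(spg$freqs[which.max(avg)] - 40), 1)
  # independent check: plain periodogram puts the peak at the same place
  p <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  expect_equal(round(f[which.max(p[2:(length(x) / 2)]) + 1]), 40)
})

test_that("single-taper mode tracks a Hann periodogram at the peak", {
  fs <- 1000
  set.seed(9)
  t <- (0:(fs * 30 - 1)) / fs
  x <- sin(2 * pi * 40 * t) + rnorm(length(t), sd = 0.1)
  rec <- mea_recording(matrix(x, 1), fs, "DG",
                       trial_meta("s", 2, onset_s = 15, duration_s = 30))
  spg <- multitaper_spectrogram(rec, spectral_config(n_tapers = 1))
  mt <- colMeans(spg$power[1, , ])
  # Hann-windowed sliding periodogram with the same windows, oracle-style
  win <- 1000
  hann <- 0.5 * (1 - cos(2 * pi * (0:(win - 1)) / (win - 1)))
  hann <- hann / sqrt(sum(hann^2))
  starts <- seq(1, length(x) - win + 1, by = 100)
  hp <- rowMeans(vapply(starts, function(s) {
    seg <- x[s:(s + win - 1)] * hann
    (2 / fs) * Mod(fft(seg))[2:501]^2
  }, numeric(500)))
  ipk <- which.max(hp)
  expect_equal(which.max(mt), ipk)
  expect_lt(abs(mt[ipk] - hp[ipk]) / hp[ipk], 0.05)
})

test_that("post-stimulus aggregation selects the right windows", {
  cfg <- generator_config(n_channels = 2L, rng_seed = 41L)
  rec <- generate_recording(cfg, trial_meta("s", 2), list())
  spg <- multitaper_spectrogram(rec)
  expect_equal(sum(spg$window_starts >= 30), 291L)
  cs <- post_stim_spectrum(spg)
  expect_s3_class(cs, "channel_spectrum")
  expect_equal(spectrum_stage(cs), "raw")
  expect_error(post_stim_spectrum(spg, onset_s = 100), "onset")
  # constant-in-time spectrogram: the mean equals any single window
  spg2 <- spg
  for (w in seq_len(dim(spg2$power)[2])) spg2$power[, w, ] <- spg2$power[, 1, ]
  cs2 <- post_stim_spectrum(spg2)
  expect_equal(matrix(cs2$power, nrow = 500)[, 1], spg2$power[1, 1, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("direct post-spectrum path equals the full spectrogram path", {
  cfg <- generator_config(n_channels = 3L, duration_s = 10, onset_s = 5,
                          rng_seed = 17L)
  rec <- generate_recording(cfg, trial_meta("s", 2, onset_s = 5,
                                            duration_s = 10),
                            c(beta = TRUE))
  rec <- highpass(rec)
  a <- meabands:::post_spectrum_direct(rec, spectral_config())
  b <- post_stim_spectrum(multitaper_spectrogram(rec, spectral_config()))
  expect_equal(a$power, b$power, tolerance = 1e-12)
  # and trimming the recording first changes nothing
  cc <- meabands:::post_spectrum_direct(trim_recording(rec, 5),
                                        spectral_config())
  expect_equal(cc$power, b$power, tolerance = 1e-12)
})

test_that("1/f correction multiplies by frequency (algebraic identity)", {
  df <- tibble::tibble(channel = 1L, freq_hz = 1:500, power = 1 / (1:500))
  cs <- as_channel_spectrum(df, stage = "raw")
  out <- correct_one_over_f(cs)
  expect_equal(out$power, rep(1, 500))
  expect_equal(spectrum_stage(out), "f_corrected")
  zero <- as_channel_spectrum(dplyr::mutate(df, power = 0), stage = "raw")
  expect_equal(correct_one_over_f(zero)$power, rep(0, 500))
})

test_that("the stage order raw -> f_corrected -> notch -> normalized is enforced", {
  df <- tibble::tibble(channel = 1L, freq_hz = 1:500, power = runif(500))
  raw <- as_channel_spectrum(df, stage = "raw")
  expect_error(excise_line_noise(raw), "stage")
  expect_error(normalize_spectrum(raw), "stage")
  fc <- correct_one_over_f(raw)
  expect_error(correct_one_over_f(fc), "stage")
  nm <- normalize_spectrum(excise_line_noise(fc))
  expect_equal(spectrum_stage(nm), "normalized")
  expect_error(correct_one_over_f(nm), "stage")
})

test_that("line-harmonic excision bridges each gap linearly", {
  # flat endpoints: a huge 50 Hz spike is flattened to the plateau level
  p <- rep(1, 500)
  p[50] <- 1000
  cs <- as_channel_spectrum(
    tibble::tibble(channel = 1L, freq_hz = 1:500, power = p), "f_corrected")
  out <- excise_line_noise(cs)
  expect_equal(out$power[48:52], rep(1, 5))
  # sloped endpoints: midpoint of the 47 -> 53 line
  p2 <- rep(1, 500)
  p2[47] <- 0; p2[53] <- 6
  p2[48:52] <- 99
  cs2 <- as_channel_spectrum(
    tibble::tibble(channel = 1L, freq_hz = 1:500, power = p2), "f_corrected")
  out2 <- excise_line_noise(cs2)
  expect_equal(out2$power[50], 3.0)
  expect_equal(out2$power[48:52], (48:52 - 47) / 6 * 6)
  # ten harmonics fall on the 1-500 Hz grid
  p3 <- rep(1, 500)
  harm <- (1:10) * 50
  p3[harm] <- 100
  cs3 <- as_channel_spectrum(
    tibble::tibble(channel = 1L, freq_hz = 1:500, power = p3), "f_corrected")
  out3 <- excise_line_noise(cs3)
  expect_true(all(out3$power[harm] < 100))
  n_changed_intervals <- sum(vapply(1:10, function(h) {
    any(out3$power[(h * 50 - 2):(min(h * 50 + 2, 500))] !=
          p3[(h * 50 - 2):(min(h * 50 + 2, 500))])
  }, logical(1)))
  expect_equal(n_changed_intervals, 10L)
})

test_that("normalization gives unit sums and flags silent channels", {
  df <- tibble::tibble(
    channel = rep(1:2, each = 2),
    freq_hz = rep(c(10, 20), 2),
    power = c(3, 1, 0, 0)
  )
  cs <- as_channel_spectrum(df, "notch_interpolated")
  out <- normalize_spectrum(cs)
  expect_equal(out$power[out$channel == 1], c(0.75, 0.25))
  expect_identical(attr(out, "inactive_channels"), 2L)
  # renormalizing an already-normalized spectrum is a no-op
  half <- as_channel_spectrum(
    tibble::tibble(channel = 1L, freq_hz = c(10, 20), power = c(0.75, 0.25)),
    "notch_interpolated")
  expect_equal(normalize_spectrum(half)$power, c(0.75, 0.25))
})

test_that("white-noise spectra are flat across 5-450 Hz", {
  fs <- 1000
  set.seed(12)
  rec <- mea_recording(matrix(rnorm(fs * 60), 1), fs, "DG",
                       trial_meta("s", 2))
  spg <- multitaper_spectrogram(rec)
  avg <- colMeans(spg$power[1, , ])
  sel <- spg$freqs >= 5 & spg$freqs <= 450
  expect_lt(max(avg[sel]) / min(avg[sel]), 2)
})

test_that("trial averaging drops the naive first trial", {
  mk <- function(tr, scale) {
    as_channel_spectrum(
      tibble::tibble(channel = 1L, freq_hz = 1:10, power = scale * (1:10)),
      "normalized",
      meta = trial_meta("cultA", tr)
    )
  }
  sp <- c(list(mk(1, 100)), lapply(2:6, mk, scale = 1))
  avg <- average_trials(sp)
  expect_equal(avg$power, 1:10)
  expect_error(average_trials(list(mk(1, 1), mk(1, 1))), "naive")
  expect_error(average_trials(list(mk(2, 1))), "at least two")
  identical6 <- lapply(rep(2:6, length.out = 6), mk, scale = 2)
  expect_equal(average_trials(identical6)$power, 2 * (1:10))
})
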