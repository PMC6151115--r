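# Synthetic multichannel LFP generator: pink + white background, line hum and
# harmonics, and narrowband oscillatory responses gated at the stimulus onset.
# The generator gives every downstream stage a ground truth to recover.

#' Per-band oscillation specification
#'
#' Describes the narrowband response the generator injects for one band:
#' its centre frequency, bandwidth (used by the filtered-noise waveform),
#' amplitude, which hippocampal areas express it, and the fraction of
#' channels within those areas that carry it.
#'
#' @param center Centre frequency in Hz; must lie inside the band's
#'   canonical range.
#' @param bandwidth Full bandwidth in Hz for the `"noise"` waveform.
#' @param amplitude Peak amplitude in signal units (microvolt scale).
#' @param areas Areas in which the oscillation can appear.
#' @param fraction Fraction of channels in those areas that become active.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(center, bandwidth = 2, amplitude = 15,
                      areas = c("DG", "CA3", "CA1"), fraction = 0.5) {
  if (amplitude < 0 || bandwidth <= 0 || fraction < 0 || fraction > 1) {
    abort("band_spec: amplitude >= 0, bandwidth > 0, fraction in [0, 1].")
  }
  structure(
    list(center = center, bandwidth = bandwidth, amplitude = amplitude,
         areas = areas, fraction = fraction),
    class = "band_spec"
  )
}

default_band_specs <- function() {
  list(
    delta = band_spec(center = 2, bandwidth = 1),
    theta = band_spec(center = 7, bandwidth = 2),
    beta  = band_spec(center = 20, bandwidth = 4),
    gamma = band_spec(center = 40, bandwidth = 8)
  )
}

# Occurrence model defaults: log-odds of per-culture band presence.
# Gamma rises with DIV (27% -> 62% -> 65% at DIV 7/13/26); delta, theta and
# beta are flat at 49%, 22% and 91%. Genotype has no effect by default.
default_occurrence_model <- function() {
  flat <- function(p) {
    list(intercept = qlogis(p),
         div = c("7" = 0, "13" = 0, "26" = 0),
         genotype_ko = 0)
  }
  gamma <- list(
    intercept = qlogis(0.27),
    div = c("7" = 0,
            "13" = qlogis(0.62) - qlogis(0.27),
            "26" = qlogis(0.65) - qlogis(0.27)),
    genotype_ko = 0
  )
  list(delta = flat(0.49), theta = flat(0.22), beta = flat(0.91), gamma = gamma)
}

#' Synthetic-recording generator configuration
#'
#' Bundles everything the generator needs: geometry (channels, sampling rate,
#' trial timing), background-noise amplitudes, line-hum harmonics, the
#' per-band oscillation specs, the logistic occurrence model, and the seed.
#'
#' Defaults emulate the study conditions: 60 electrodes split 20/20/20 into
#' DG/CA3/CA1, 60 s trials with the stimulus at 30 s, 1/f background with a
#' 50 Hz hum and two harmonics, oscillations at 3/7/20/40 Hz in half of the
#' channels of every area, and occurrence probabilities of 49/22/91% for
#' delta/theta/beta at every DIV and 27/62/65% for gamma at DIV 7/13/26.
#'
#' @param n_channels Number of electrodes (default 60).
#' @param fs Sampling rate in Hz, 1000 (pre-decimated) or 20000 (raw).
#' @param duration_s Trial length in seconds.
#' @param onset_s Stimulus onset in seconds.
#' @param pink_noise_amplitude RMS of the 1/f background per channel.
#' @param white_noise_amplitude SD of the white background per channel.
#' @param hum_freq_hz Line frequency (default 50).
#' @param hum_harmonic_amplitudes Amplitudes of the line frequency and its
#'   integer harmonics (default 5, 2.5, 1.25 at 50/100/150 Hz).
#' @param bands Named list of [band_spec()]s for delta/theta/beta/gamma.
#' @param occurrence Per-band logistic occurrence model (intercept, per-DIV
#'   log-odds offsets, KO genotype offset).
#' @param osc_waveform `"sine"` (default; random-phase sinusoid at the band
#'   centre) or `"noise"` (band-pass-filtered Gaussian noise).
#' @param ramp_s Linear onset ramp length in seconds (default 0.5).
#' @param channel_area Optional per-channel area labels; default is a
#'   20/20/20 DG/CA3/CA1 partition.
#' @param rng_seed Integer seed making generation reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_channels = 60L,
                             fs = 1000,
                             duration_s = 60,
                             onset_s = 30,
                             pink_noise_amplitude = 10,
                             white_noise_amplitude = 2,
                             hum_freq_hz = 50,
                             hum_harmonic_amplitudes = c(5, 2.5, 1.25),
                             bands = default_band_specs(),
                             occurrence = default_occurrence_model(),
                             osc_waveform = c("sine", "noise"),
                             ramp_s = 0.5,
                             channel_area = NULL,
                             rng_seed = 1L) {
  osc_waveform <- match.arg(osc_waveform)
  if (!fs %in% c(1000, 20000)) {
    abort("`fs` must be 1000 or 20000 for generated data.")
  }
  if (pink_noise_amplitude < 0 || white_noise_amplitude < 0 ||
      any(hum_harmonic_amplitudes < 0)) {
    abort("Noise and hum amplitudes must be >= 0.")
  }
  n_samp <- fs * duration_s
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    abort(sprintf("fs x duration_s = %g is not an integer sample count.", n_samp))
  }
  br <- band_ranges()
  for (b in names(bands)) {
    if (!b %in% .band_names) abort(sprintf("Unknown band name: %s", b))
    rng <- br[br$band == b, ]
    ctr <- bands[[b]]$center
    if (ctr < rng$fmin || ctr > rng$fmax) {
      abort(sprintf("Band %s centre %g Hz lies outside its range %g-%g Hz.",
                    b, ctr, rng$fmin, rng$fmax))
    }
  }
  if (is.null(channel_area)) {
    channel_area <- rep(c("DG", "CA3", "CA1"), each = ceiling(n_channels / 3))[
      seq_len(n_channels)]
  }
  if (length(channel_area) != n_channels) {
    abort("`channel_area` must have one label per channel.")
  }
  structure(
    list(
      n_channels = as.integer(n_channels), fs = fs,
      duration_s = duration_s, onset_s = onset_s,
      pink_noise_amplitude = pink_noise_amplitude,
      white_noise_amplitude = white_noise_amplitude,
      hum_freq_hz = hum_freq_hz,
      hum_harmonic_amplitudes = hum_harmonic_amplitudes,
      bands = bands, occurrence = occurrence,
      osc_waveform = osc_waveform, ramp_s = ramp_s,
      channel_area = channel_area,
      rng_seed = as.integer(rng_seed)
    ),
    class = "generator_config"
  )
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1/f background: frequency-domain shaping with amplitude ~ 1/sqrt(f) for
# f >= 1 Hz, zero below 1 Hz and at DC, uniform random phases. The returned
# signal is rescaled to the requested RMS.
pink_noise <- function(n, fs, rms) {
  pink_noise_matrix(n, fs, rms, 1L)[, 1]
}

# one column per channel; a single seeded runif draw covers all channels.
# Channel pairs share one inverse FFT: both spectra are conjugate-symmetric,
# so ifft(S1 + i S2) = x1 + i x2 with x1, x2 real.
pink_noise_matrix <- function(n, fs, rms, n_chan) {
  if (rms == 0) return(matrix(0, n, n_chan))
  freqs <- seq(0, floor(n / 2)) * fs / n
  amp <- ifelse(freqs >= 1, 1 / sqrt(freqs), 0)
  nf <- length(freqs)
  phase <- matrix(runif(nf * n_chan, 0, 2 * pi), nf, n_chan)
  half <- amp * exp(1i * phase)
  half[1, ] <- 0
  if (n %% 2 == 0) half[nf, ] <- amp[nf] # Nyquist bin must be real
  spec <- rbind(half,
                Conj(half[(nf - 1 + n %% 2):2, , drop = FALSE]))
  x <- matrix(0, n, n_chan)
  odd <- seq(1L, n_chan, by = 2L)
  odd <- odd[odd < n_chan]
  if (length(odd)) {
    Z <- mvfft(spec[, odd, drop = FALSE] +
                 (0 + 1i) * spec[, odd + 1L, drop = FALSE],
               inverse = TRUE) / n
    x[, odd] <- Re(Z)
    x[, odd + 1L] <- Im(Z)
  }
  if (n_chan %% 2 == 1) {
    x[, n_chan] <- Re(fft(spec[, n_chan], inverse = TRUE)) / n
  }
  sweep(x, 2, rms / sqrt(colMeans(x^2)), "*")
}

# Band-pass-filtered Gaussian noise scaled so its RMS matches a sinusoid of
# the given amplitude (amplitude / sqrt(2)).
bandpass_noise <- function(n, fs, center, bandwidth, amplitude) {
  lo <- max(center - bandwidth / 2, 0.5)
  hi <- min(center + bandwidth / 2, fs / 2 * 0.99)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- rnorm(n)
  y <- signal::filtfilt(bf, x)
  y * (amplitude / sqrt(2)) / sd(y)
}

# 0 before onset, linear 0 -> 1 over [onset, onset + ramp], 1 afterwards.
onset_ramp <- function(t, onset_s, ramp_s) {
  pmin(pmax((t - onset_s) / max(ramp_s, .Machine$double.eps), 0), 1)
}

#' Generate one synthetic trial
#'
#' Builds a channels x samples recording consisting of per-channel pink
#' (1/f) and white background noise, line hum and harmonics shared across
#' channels, and -- for each band flagged present -- a narrowband oscillation
#' added to a random subset of channels in the band's configured areas,
#' starting at the stimulus onset with a short linear ramp. Identical
#' `(config, meta, band_presence, seed)` give bit-identical output.
#'
#' @param config A [generator_config()].
#' @param meta A [trial_meta()].
#' @param band_presence Named logical vector/list over a subset of
#'   delta/theta/beta/gamma; bands not named are absent.
#' @param seed Overrides `config$rng_seed` when given.
#' @param active_channels Optional named list mapping band to the channel
#'   indices carrying it; by default a fresh random subset is drawn. A
#'   culture's trials share one electrode layout, so [generate_culture()]
#'   draws the subsets once per culture and passes them here.
#' @return An [mea_recording()].
#' @export
#' @examples
#' cfg <- generator_config(n_channels = 6, duration_s = 4, onset_s = 2)
#' rec <- generate_recording(cfg, trial_meta("c1", onset_s = 2, duration_s = 4),
#'                           c(gamma = TRUE))
#' dim(rec$signal)
generate_recording <- function(config, meta, band_presence = list(),
                               seed = NULL, active_channels = NULL) {
  stopifnot(inherits(config, "generator_config"))
  bp <- unlist(band_presence)
  bad <- setdiff(names(bp), .band_names)
  if (length(bad) > 0) {
    abort(sprintf("Unknown band name(s) in `band_presence`: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!isTRUE(all.equal(meta$duration_s, config$duration_s)) ||
      !isTRUE(all.equal(meta$onset_s, config$onset_s))) {
    abort("Trial timing in `meta` disagrees with the generator config.")
  }
  n <- config$fs * config$duration_s
  if (abs(n - round(n)) > 1e-9) {
    abort("fs x duration_s is not an integer sample count.")
  }
  n <- as.integer(round(n))
  nc <- config$n_channels
  seed <- seed %||% config$rng_seed

  with_rng_seed(seed, {
    # built samples x channels (column ops are cheap), transposed at the end
    t <- (seq_len(n) - 1) / config$fs
    if (config$pink_noise_amplitude > 0) {
      sigT <- pink_noise_matrix(n, config$fs, config$pink_noise_amplitude, nc)
    } else {
      sigT <- matrix(0, n, nc)
    }
    if (config$white_noise_amplitude > 0) {
      sigT <- sigT + rnorm(n * nc, sd = config$white_noise_amplitude)
    }

    # line hum: one shared source, so identical phase on every channel
    ha <- config$hum_harmonic_amplitudes
    hum <- numeric(n)
    any_hum <- FALSE
    for (h in seq_along(ha)) {
      fh <- h * config$hum_freq_hz
      if (ha[h] > 0 && fh < config$fs / 2) {
        hum <- hum + ha[h] * sin(2 * pi * fh * t + runif(1, 0, 2 * pi))
        any_hum <- TRUE
      }
    }
    if (any_hum) sigT <- sigT + hum # recycles down each column

    ramp <- onset_ramp(t, config$onset_s, config$ramp_s)
    active_map <- list()
    for (b in names(bp)) {
      if (!isTRUE(bp[[b]])) next
      spec <- config$bands[[b]]
      if (is.null(spec) || spec$amplitude == 0) next
      if (!is.null(active_channels[[b]])) {
        act <- sort(active_channels[[b]])
      } else {
        eligible <- which(config$channel_area %in% spec$areas)
        act <- sort(sample(eligible, round(spec$fraction * length(eligible))))
      }
      active_map[[b]] <- act
      if (config$osc_waveform == "sine") {
        # sin(wt + phi) = sin(wt) cos(phi) + cos(wt) sin(phi): the carrier is
        # computed once per band, each channel adds its random-phase combo
        sw <- sin(2 * pi * spec$center * t) * ramp
        cw <- cos(2 * pi * spec$center * t) * ramp
        phi <- runif(length(act), 0, 2 * pi)
        for (i in seq_along(act)) {
          sigT[, act[i]] <- sigT[, act[i]] +
            spec$amplitude * (cos(phi[i]) * sw + sin(phi[i]) * cw)
        }
      } else {
        for (ch in act) {
          osc <- bandpass_noise(n, config$fs, spec$center, spec$bandwidth,
                                spec$amplitude)
          sigT[, ch] <- sigT[, ch] + ramp * osc
        }
      }
    }

    rec <- mea_recording(t(sigT), config$fs, config$channel_area, meta)
    attr(rec, "band_presence") <- bp
    attr(rec, "active_channels") <- active_map
    rec
  })
}

#' Per-band occurrence probability under the generator's logistic model
#'
#' @param config A [generator_config()].
#' @param band Band name.
#' @param genotype `"WT"` or `"KO"`.
#' @param div Days in vitro (must be a level of the model's DIV offsets).
#' @return Probability in (0, 1).
#' @export
occurrence_probability <- function(config, band, genotype, div) {
  m <- config$occurrence[[band]]
  if (is.null(m)) abort(sprintf("No occurrence model for band %s.", band))
  dv <- m$div[[as.character(div)]]
  if (is.null(dv)) dv <- 0
  eta <- m$intercept + dv + if (genotype == "KO") m$genotype_ko else 0
  plogis(eta)
}

#' Draw a cohort's ground-truth band presence
#'
#' For every genotype x DIV cell, draws `n_cultures_per_cell` cultures and,
#' per culture and band, a Bernoulli presence flag with probability given by
#' the generator's logistic occurrence model. Presence is a per-culture
#' property: all trials of a culture share it.
#'
#' @param config A [generator_config()].
#' @param n_cultures_per_cell Cultures per genotype x DIV cell.
#' @param divs DIV levels (default 7, 13, 26).
#' @param genotypes Genotype levels (default WT, KO).
#' @param seed Master seed; per-culture sub-seeds are derived from it.
#' @return A tibble with one row per culture x band: `culture_id`,
#'   `genotype`, `div`, `culture_seed`, `band`, `present`.
#' @export
draw_cohort <- function(config, n_cultures_per_cell, divs = c(7, 13, 26),
                        genotypes = c("WT", "KO"), seed = config$rng_seed) {
  if (length(divs) == 0 || length(genotypes) == 0) {
    abort("`divs` and `genotypes` must be non-empty.")
  }
  if (n_cultures_per_cell < 1) abort("`n_cultures_per_cell` must be >= 1.")
  cells <- expand.grid(div = divs, genotype = genotypes,
                       culture = seq_len(n_cultures_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cult <- nrow(cells)
  with_rng_seed(seed, {
    culture_seeds <- sample.int(.Machine$integer.max - 1L, n_cult)
    per_band <- lapply(.band_names, function(b) {
      p <- vapply(seq_len(n_cult), function(i) {
        occurrence_probability(config, b, cells$genotype[i], cells$div[i])
      }, numeric(1))
      rbinom(n_cult, 1, p) == 1
    })
    names(per_band) <- .band_names
    base <- tibble(
      culture_id = sprintf("%s_div%02d_c%04d", cells$genotype, cells$div,
                           cells$culture),
      genotype = cells$genotype, div = as.integer(cells$div),
      culture_seed = culture_seeds
    )
    out <- tidyr::expand_grid(base, band = factor(.band_names,
                                                  levels = .band_names))
    out$present <- as.vector(t(do.call(cbind, per_band)))
    out
  })
}

#' Generate all trials of one culture
#'
#' @param config A [generator_config()].
#' @param culture_truth Rows of a [draw_cohort()] tibble for one culture.
#' @param n_trials Trials to generate (default 6; trial 1 is flagged naive).
#' @param trial_indices Which trial indices to realise (default all of
#'   `1:n_trials`); a simulation that analyses only non-naive trials can
#'   skip materialising trial 1. A given trial index yields the same
#'   recording whichever subset is requested.
#' @return List of [mea_recording()]s.
#' @export
generate_culture <- function(config, culture_truth, n_trials = 6L,
                             trial_indices = seq_len(n_trials)) {
  stopifnot(nrow(culture_truth) >= 1, length(unique(culture_truth$culture_id)) == 1)
  bp <- stats::setNames(culture_truth$present, as.character(culture_truth$band))
  info <- culture_truth[1, ]
  # the electrode layout is fixed per culture: draw active subsets once
  act <- with_rng_seed(info$culture_seed, {
    out <- list()
    for (b in names(bp)) {
      if (!isTRUE(bp[[b]])) next
      spec <- config$bands[[b]]
      if (is.null(spec) || spec$amplitude == 0) next
      eligible <- which(config$channel_area %in% spec$areas)
      out[[b]] <- sort(sample(eligible, round(spec$fraction * length(eligible))))
    }
    out
  })
  lapply(trial_indices, function(tr) {
    meta <- trial_meta(info$culture_id, trial_index = tr,
                       genotype = info$genotype, div = info$div,
                       onset_s = config$onset_s, duration_s = config$duration_s)
    generate_recording(config, meta, bp,
                       seed = (info$culture_seed + tr - 1L) %% .Machine$integer.max,
                       active_channels = act)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws per-culture band presence via [draw_cohort()] and materialises
#' `n_trials` recordings per culture. Intended for small cohorts; for large
#' simulation studies draw the truth once and realise recordings one culture
#' at a time with [generate_culture()].
#'
#' @inheritParams draw_cohort
#' @param n_trials Trials per culture (default 6; trial 1 flagged naive).
#' @return A list with elements `truth` (the [draw_cohort()] tibble) and
#'   `cultures` (named list of per-culture recording lists).
#' @export
generate_cohort <- function(config, n_cultures_per_cell, divs = c(7, 13, 26),
                            genotypes = c("WT", "KO"),
                            seed = config$rng_seed, n_trials = 6L) {
  truth <- draw_cohort(config, n_cultures_per_cell, divs, genotypes, seed)
  ids <- unique(truth$culture_id)
  cultures <- lapply(ids, function(id) {
    generate_culture(config, truth[truth$culture_id == id, ], n_trials)
  })
  names(cultures) <- ids
  list(truth = truth, cultures = cultures)
}
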