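# Sliding-window DPSS multitaper spectral estimation, then the per-channel
# post-stimulus spectrum pipeline: 1/f correction -> line-harmonic excision
# -> per-channel normalization. The stage of each spectrum is recorded and
# enforced so the steps can only run in this order.

#' Spectral-analysis configuration
#'
#' @param window_s Sliding-window length in seconds (default 1, giving a
#'   1 Hz frequency grid).
#' @param step_s Window shift in seconds (default 0.1).
#' @param fmin,fmax Analysed frequency range in Hz (defaults 1 and 500).
#' @param smoothing_hw Spectral smoothing half-bandwidth W in Hz (default 2);
#'   the multitaper time-bandwidth product is `NW = window_s * W` and the
#'   default taper count is `K = 2 NW - 1`.
#' @param line_freq Line (hum) frequency in Hz (default 50).
#' @param line_hw Half-width of the excised interval around each line
#'   harmonic in Hz (default 3).
#' @param ref_band Reference band in Hz for relative peak power
#'   (default `c(200, 250)`, endpoints inclusive).
#' @param n_tapers Taper count override (default `NULL` = `2 NW - 1`).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 1, step_s = 0.1, fmin = 1, fmax = 500,
                            smoothing_hw = 2, line_freq = 50, line_hw = 3,
                            ref_band = c(200, 250), n_tapers = NULL) {
  if (length(n_tapers) == 0) n_tapers <- NULL # e.g. after a JSON round trip
  if (smoothing_hw <= 0 || line_hw <= 0) {
    abort("`smoothing_hw` and `line_hw` must be positive.")
  }
  if (!(ref_band[1] > fmin && ref_band[2] < fmax) &&
      !(ref_band[1] >= fmin && ref_band[2] <= fmax)) {
    abort("`ref_band` must lie within [fmin, fmax].")
  }
  structure(
    list(window_s = window_s, step_s = step_s, fmin = fmin, fmax = fmax,
         smoothing_hw = smoothing_hw, line_freq = line_freq,
         line_hw = line_hw, ref_band = ref_band, n_tapers = n_tapers),
    class = "spectral_config"
  )
}

# ---- DPSS (Slepian) tapers --------------------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric-tridiagonal eigenproblem. Tapers
#' are unit-energy, mutually orthonormal, and ordered by spectral
#' concentration; signs follow the usual convention (non-negative mean for
#' symmetric tapers, positive first lobe otherwise). Results are cached.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (e.g. 2 for a 1 s window smoothed over
#'   +/- 2 Hz).
#' @param k Number of tapers.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  if (k >= n) abort("Need k < n tapers.")
  w <- nw / n
  tt <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if (abs(s) > 1e-10) {
      if (s < 0) v[, j] <- -v[, j]
    } else if (v[2, j] - v[1, j] < 0) {
      v[, j] <- -v[, j]
    }
  }
  .dpss_cache[[key]] <- v
  v
}

# ---- Spectrogram ------------------------------------------------------------

# Sliding-window power for one channel, all tapers averaged. Two tapers are
# packed into one complex FFT (real and imaginary parts): for real u, v and
# Z = FFT(u + iv), |FFT(u)|^2 + |FFT(v)|^2 = (|Z|^2 + |Z_rev|^2) / 2 where
# Z_rev is Z at the conjugate-symmetric bins, so no unpacking is needed.
channel_spectrogram_power <- function(x, starts, win_n, tapers, keep_bins) {
  n_win <- length(starts)
  idx <- outer(seq_len(win_n) - 1L, starts, "+")
  X <- matrix(x[idx], nrow = win_n)
  k <- ncol(tapers)
  conj_idx <- c(1L, win_n:2L)
  conj_keep <- conj_idx[keep_bins]
  P <- matrix(0, nrow = length(keep_bins), ncol = n_win)
  j <- 1L
  while (j <= k) {
    if (j < k) {
      Z <- mvfft(X * tapers[, j] + (0 + 1i) * (X * tapers[, j + 1]))
      M <- Re(Z)^2 + Im(Z)^2
      P <- P + (M[keep_bins, , drop = FALSE] +
                  M[conj_keep, , drop = FALSE]) / 2
      j <- j + 2L
    } else {
      Fj <- mvfft(X * tapers[, j])
      P <- P + Re(Fj[keep_bins, , drop = FALSE])^2 +
        Im(Fj[keep_bins, , drop = FALSE])^2
      j <- j + 1L
    }
  }
  P / k
}

# Two channels at once: taper pairs are packed within each channel as in
# channel_spectrogram_power; an odd final taper is packed across the two
# channels and unpacked by conjugate symmetry.
pair_spectrogram_power <- function(xa, xb, starts, win_n, tapers, keep_bins) {
  n_win <- length(starts)
  idx <- outer(seq_len(win_n) - 1L, starts, "+")
  Xa <- matrix(xa[idx], nrow = win_n)
  Xb <- matrix(xb[idx], nrow = win_n)
  k <- ncol(tapers)
  conj_idx <- c(1L, win_n:2L)
  conj_keep <- conj_idx[keep_bins]
  Pa <- Pb <- matrix(0, nrow = length(keep_bins), ncol = n_win)
  j <- 1L
  while (j + 1L <= k) {
    for (side in 1:2) {
      X <- if (side == 1) Xa else Xb
      Z <- mvfft(X * tapers[, j] + (0 + 1i) * (X * tapers[, j + 1]))
      M <- Re(Z)^2 + Im(Z)^2
      add <- (M[keep_bins, , drop = FALSE] +
                M[conj_keep, , drop = FALSE]) / 2
      if (side == 1) Pa <- Pa + add else Pb <- Pb + add
    }
    j <- j + 2L
  }
  if (j == k) {
    Z <- mvfft(Xa * tapers[, k] + (0 + 1i) * (Xb * tapers[, k]))
    Fa <- (Z[keep_bins, , drop = FALSE] +
             Conj(Z[conj_keep, , drop = FALSE])) / 2
    Fb <- (Z[keep_bins, , drop = FALSE] -
             Conj(Z[conj_keep, , drop = FALSE])) / (0 + 2i)
    Pa <- Pa + Re(Fa)^2 + Im(Fa)^2
    Pb <- Pb + Re(Fb)^2 + Im(Fb)^2
  }
  list(Pa / k, Pb / k)
}

#' DPSS multitaper short-time spectrogram
#'
#' Slides a window of `window_s` seconds in steps of `step_s` over each
#' channel, computing at each position the average of K DPSS-tapered
#' periodograms with time-bandwidth product `NW = window_s * smoothing_hw`
#' and `K = 2 NW - 1` tapers. The frequency grid is `fmin` to `fmax` at
#' `1 / window_s` Hz spacing (1 Hz at the defaults).
#'
#' @param rec An [mea_recording()] (expected at 1000 Hz after
#'   preprocessing).
#' @param cfg A [spectral_config()].
#' @return An object of class `mea_spectrogram`: a list with `power`
#'   (channels x windows x frequencies), `freqs` (Hz), `window_starts`
#'   (seconds), `channel_area`, and `meta`.
#' @export
multitaper_spectrogram <- function(rec, cfg = spectral_config()) {
  stopifnot(inherits(rec, "mea_recording"))
  fs <- rec$fs
  win_n <- as.integer(round(cfg$window_s * fs))
  step_n <- cfg$step_s * fs
  n <- n_samples(rec)
  if (n < win_n) abort("Recording is shorter than one analysis window.")
  n_win <- as.integer(floor((n - win_n) / step_n + 1e-9)) + 1L
  starts <- as.integer(round((seq_len(n_win) - 1L) * step_n)) + 1L
  df <- fs / win_n
  all_freqs <- (seq_len(win_n) - 1L) * df
  keep_bins <- which(all_freqs >= cfg$fmin - 1e-9 &
                       all_freqs <= min(cfg$fmax, fs / 2) + 1e-9)
  freqs <- all_freqs[keep_bins]
  nw <- cfg$window_s * cfg$smoothing_hw
  k <- cfg$n_tapers %||% as.integer(2 * nw - 1)
  if (k < 1) abort("Taper count must be at least 1.")
  tapers <- dpss_tapers(win_n, nw, k)
  # one-sided PSD scaling (doubling skipped at the Nyquist bin)
  scale <- ifelse(abs(freqs - fs / 2) < 1e-9, 1, 2) / fs
  nc <- n_channels(rec)
  power <- array(0, dim = c(nc, n_win, length(freqs)))
  for (ch in seq_len(nc)) {
    P <- channel_spectrogram_power(rec$signal[ch, ], starts, win_n, tapers,
                                   keep_bins)
    power[ch, , ] <- t(P * scale)
  }
  structure(
    list(power = power, freqs = freqs,
         window_starts = (rec$t_start %||% 0) + (starts - 1L) / fs,
         channel_area = rec$channel_area, meta = rec$meta),
    class = "mea_spectrogram"
  )
}

#' @export
print.mea_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<mea_spectrogram> %d channels x %d windows x %d frequencies (%g-%g Hz)\n",
    dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
    min(x$freqs), max(x$freqs)
  ))
  invisible(x)
}

#' Tidy a spectrogram into long format
#'
#' @param x An `mea_spectrogram`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `area`, `window_start_s`,
#'   `freq_hz`, `power`.
#' @export
as_tibble.mea_spectrogram <- function(x, ...) {
  d <- dim(x$power)
  tibble(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    area = rep(x$channel_area, times = d[2] * d[3]),
    window_start_s = rep(rep(x$window_starts, each = d[1]), times = d[3]),
    freq_hz = rep(x$freqs, each = d[1] * d[2]),
    power = as.vector(x$power)
  )
}

# ---- ChannelSpectrum --------------------------------------------------------

# A channel_spectrum is a tibble (channel, area, freq_hz, power), sorted
# channel-major, carrying its pipeline stage as an attribute.
new_channel_spectrum <- function(channel, area, freq_hz, power, stage,
                                 meta = NULL, inactive_channels = integer()) {
  df <- tibble(channel = channel, area = area, freq_hz = freq_hz,
               power = power)
  df <- arrange(df, .data$channel, .data$freq_hz)
  structure(
    df,
    stage = stage, meta = meta, inactive_channels = inactive_channels,
    class = c("channel_spectrum", class(tibble()))
  )
}

#' Build a channel spectrum from a data frame
#'
#' Constructs a `channel_spectrum` (the tibble the spectral pipeline stages
#' consume and produce) from columns `channel`, `freq_hz`, `power` and
#' optionally `area`. Useful for feeding externally computed spectra into
#' the detection stage.
#'
#' @param df Data frame with columns `channel`, `freq_hz`, `power`, and
#'   optionally `area`.
#' @param stage Pipeline stage of the values: `"raw"`, `"f_corrected"`,
#'   `"notch_interpolated"` or `"normalized"`.
#' @param meta Optional [trial_meta()]-like list.
#' @return A `channel_spectrum` tibble.
#' @export
as_channel_spectrum <- function(df, stage = "raw", meta = NULL) {
  stage <- match.arg(stage, c("raw", "f_corrected", "notch_interpolated",
                              "normalized"))
  need <- c("channel", "freq_hz", "power")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  }
  area <- if ("area" %in% names(df)) df$area else rep("DG", nrow(df))
  new_channel_spectrum(df$channel, area, df$freq_hz, df$power,
                       stage = stage, meta = meta)
}

#' Pipeline stage of a channel spectrum
#' @param cs A `channel_spectrum`.
#' @return One of `"raw"`, `"f_corrected"`, `"notch_interpolated"`,
#'   `"normalized"`.
#' @export
spectrum_stage <- function(cs) attr(cs, "stage")

check_stage <- function(cs, expected, op) {
  if (!inherits(cs, "channel_spectrum")) {
    abort(sprintf("%s() expects a channel_spectrum.", op))
  }
  st <- spectrum_stage(cs)
  if (!st %in% expected) {
    abort(sprintf(
      "%s() requires stage %s but got \"%s\"; the pipeline order is raw -> f_corrected -> notch_interpolated -> normalized.",
      op, paste(sprintf('"%s"', expected), collapse = " or "), st
    ))
  }
  invisible(cs)
}

# power as an n_freq x n_channel matrix plus the channel/freq/area vectors
cs_matrix <- function(cs) {
  chans <- unique(cs$channel)
  freqs <- unique(cs$freq_hz)
  P <- matrix(cs$power, nrow = length(freqs), ncol = length(chans))
  list(P = P, freqs = freqs, channels = chans,
       areas = cs$area[match(chans, cs$channel)])
}

cs_rebuild <- function(m, stage, template) {
  new_channel_spectrum(
    channel = rep(m$channels, each = length(m$freqs)),
    area = rep(m$areas, each = length(m$freqs)),
    freq_hz = rep(m$freqs, times = length(m$channels)),
    power = as.vector(m$P),
    stage = stage, meta = attr(template, "meta"),
    inactive_channels = attr(template, "inactive_channels") %||% integer()
  )
}

# Fast path for the mean post-stimulus spectrum: identical to
# post_stim_spectrum(multitaper_spectrogram(rec), onset, "mean") but the
# window x frequency power array is averaged channel-by-channel instead of
# being materialised (the full array is ~70 MB per 60-channel trial).
post_spectrum_direct <- function(rec, cfg, onset_s = rec$meta$onset_s) {
  stopifnot(inherits(rec, "mea_recording"))
  fs <- rec$fs
  win_n <- as.integer(round(cfg$window_s * fs))
  step_n <- cfg$step_s * fs
  n <- n_samples(rec)
  if (n < win_n) abort("Recording is shorter than one analysis window.")
  n_win <- as.integer(floor((n - win_n) / step_n + 1e-9)) + 1L
  starts <- as.integer(round((seq_len(n_win) - 1L) * step_n)) + 1L
  start_times <- (rec$t_start %||% 0) + (starts - 1L) / fs
  sel <- which(start_times >= onset_s - 1e-9)
  if (length(sel) == 0) {
    abort("No analysis window starts at or after the stimulus onset.")
  }
  df <- fs / win_n
  all_freqs <- (seq_len(win_n) - 1L) * df
  keep_bins <- which(all_freqs >= cfg$fmin - 1e-9 &
                       all_freqs <= min(cfg$fmax, fs / 2) + 1e-9)
  freqs <- all_freqs[keep_bins]
  nw <- cfg$window_s * cfg$smoothing_hw
  k <- cfg$n_tapers %||% as.integer(2 * nw - 1)
  tapers <- dpss_tapers(win_n, nw, k)
  scale <- ifelse(abs(freqs - fs / 2) < 1e-9, 1, 2) / fs
  nc <- n_channels(rec)
  agg <- matrix(0, nrow = length(freqs), ncol = nc)
  ch <- 1L
  while (ch <= nc) {
    if (ch < nc) {
      PP <- pair_spectrogram_power(rec$signal[ch, ], rec$signal[ch + 1L, ],
                                   starts[sel], win_n, tapers, keep_bins)
      agg[, ch] <- rowMeans(PP[[1]]) * scale
      agg[, ch + 1L] <- rowMeans(PP[[2]]) * scale
      ch <- ch + 2L
    } else {
      P <- channel_spectrogram_power(rec$signal[ch, ], starts[sel], win_n,
                                     tapers, keep_bins)
      agg[, ch] <- rowMeans(P) * scale
      ch <- ch + 1L
    }
  }
  new_channel_spectrum(
    channel = rep(seq_len(nc), each = length(freqs)),
    area = rep(rec$channel_area, each = length(freqs)),
    freq_hz = rep(freqs, times = nc),
    power = as.vector(agg),
    stage = "raw", meta = rec$meta
  )
}

#' Post-stimulus per-channel spectrum
#'
#' Averages the spectrogram over all windows whose start time is at or after
#' the stimulus onset, yielding one spectrum per channel (stage `"raw"`).
#'
#' @param spg An `mea_spectrogram`.
#' @param onset_s Stimulus onset in seconds (default: from the recording's
#'   metadata).
#' @param stat Aggregation over windows: `"mean"` (default) or `"median"`.
#' @return A `channel_spectrum` tibble at stage `"raw"`.
#' @export
post_stim_spectrum <- function(spg, onset_s = NULL, stat = c("mean", "median")) {
  stopifnot(inherits(spg, "mea_spectrogram"))
  stat <- match.arg(stat)
  onset_s <- onset_s %||% spg$meta$onset_s
  sel <- which(spg$window_starts >= onset_s - 1e-9)
  if (length(sel) == 0) {
    abort("No analysis window starts at or after the stimulus onset.")
  }
  sub <- spg$power[, sel, , drop = FALSE]
  d <- dim(sub)
  agg <- if (stat == "mean") {
    dim(sub) <- c(d[1] * d[2], d[3])
    rowsum(sub, group = rep(seq_len(d[1]), times = d[2])) / d[2]
  } else {
    apply(sub, c(1, 3), median)
  }
  nc <- dim(agg)[1]
  new_channel_spectrum(
    channel = rep(seq_len(nc), each = length(spg$freqs)),
    area = rep(spg$channel_area, each = length(spg$freqs)),
    freq_hz = rep(spg$freqs, times = nc),
    power = as.vector(t(agg)),
    stage = "raw", meta = spg$meta
  )
}

#' Multiply the spectrum by frequency to correct for 1/f background
#'
#' The 1/f background of field potentials falls as `1/f`; multiplying each
#' power value by its frequency flattens that background so narrowband peaks
#' stand out uniformly across the spectrum.
#'
#' @param cs A `channel_spectrum` at stage `"raw"`.
#' @return A `channel_spectrum` at stage `"f_corrected"`.
#' @export
correct_one_over_f <- function(cs) {
  check_stage(cs, "raw", "correct_one_over_f")
  out <- mutate(as_tibble(cs), power = .data$power * .data$freq_hz)
  new_channel_spectrum(out$channel, out$area, out$freq_hz, out$power,
                       stage = "f_corrected", meta = attr(cs, "meta"))
}

#' Excise line-hum harmonics and bridge the gaps linearly
#'
#' For every harmonic of the line frequency inside the analysed range,
#' power on the open interval (harmonic - line_hw, harmonic + line_hw) is
#' replaced by linear interpolation between the values at the interval's
#' boundary grid points. A boundary falling outside the grid clips the
#' interval (the remaining anchor's value is extended flat); a harmonic
#' entirely outside the range is skipped.
#'
#' @param cs A `channel_spectrum` at stage `"f_corrected"`.
#' @param cfg A [spectral_config()] (or pass `line_freq`/`line_hw`).
#' @param line_freq,line_hw Line frequency and half-width in Hz.
#' @return A `channel_spectrum` at stage `"notch_interpolated"`.
#' @export
excise_line_noise <- function(cs, cfg = spectral_config(),
                              line_freq = cfg$line_freq,
                              line_hw = cfg$line_hw) {
  check_stage(cs, "f_corrected", "excise_line_noise")
  m <- cs_matrix(cs)
  fmin <- min(m$freqs); fmax <- max(m$freqs)
  h <- 1
  while (h * line_freq - line_hw <= fmax + 1e-9) {
    f0 <- h * line_freq
    lo <- f0 - line_hw; hi <- f0 + line_hw
    if (hi > fmin - 1e-9) { # interval intersects the grid
      interior <- which(m$freqs > lo + 1e-9 & m$freqs < hi - 1e-9)
      li <- which(abs(m$freqs - lo) < 1e-6)
      ri <- which(abs(m$freqs - hi) < 1e-6)
      if (length(interior) > 0) {
        if (length(li) == 1 && length(ri) == 1) {
          wgt <- (m$freqs[interior] - lo) / (hi - lo)
          m$P[interior, ] <- outer(1 - wgt, m$P[li, ]) + outer(wgt, m$P[ri, ])
        } else if (length(li) == 1) {
          m$P[interior, ] <- outer(rep(1, length(interior)), m$P[li, ])
        } else if (length(ri) == 1) {
          m$P[interior, ] <- outer(rep(1, length(interior)), m$P[ri, ])
        }
      }
    }
    h <- h + 1
  }
  cs_rebuild(m, "notch_interpolated", cs)
}

#' Normalize each channel's spectrum to unit sum
#'
#' Divides every value by the sum of that channel's spectrum, so each
#' channel's spectrum becomes a distribution over frequency (sums to 1).
#' Channels with an all-zero spectrum cannot be normalized; they are left at
#' zero and flagged as inactive (attribute `inactive_channels`), to be
#' excluded from detection.
#'
#' @param cs A `channel_spectrum` at stage `"notch_interpolated"`.
#' @return A `channel_spectrum` at stage `"normalized"`.
#' @export
normalize_spectrum <- function(cs) {
  check_stage(cs, "notch_interpolated", "normalize_spectrum")
  m <- cs_matrix(cs)
  sums <- colSums(m$P)
  inactive <- m$channels[sums <= 0]
  pos <- sums > 0
  m$P[, pos] <- sweep(m$P[, pos, drop = FALSE], 2, sums[pos], "/")
  out <- cs_rebuild(m, "normalized", cs)
  attr(out, "inactive_channels") <-
    sort(unique(c(attr(cs, "inactive_channels") %||% integer(), inactive)))
  out
}

#' Average spectra over a culture's non-naive trials
#'
#' Drops every spectrum whose trial index is 1 (the carbachol-naive control
#' trial) and returns the element-wise mean of the remaining trials'
#' spectra. All spectra must come from the same culture, share the same
#' stage, and lie on the same channel/frequency grid.
#'
#' @param spectra List of `channel_spectrum` objects, one per trial.
#' @return A single `channel_spectrum` at the input stage, with trial-level
#'   metadata replaced by culture-level metadata.
#' @export
average_trials <- function(spectra) {
  if (length(spectra) < 2) abort("Need at least two trial spectra to average.")
  stages <- vapply(spectra, spectrum_stage, character(1))
  if (length(unique(stages)) != 1) {
    abort("All trial spectra must be at the same pipeline stage.")
  }
  metas <- lapply(spectra, attr, "meta")
  ids <- vapply(metas, function(m) m$culture_id, character(1))
  if (length(unique(ids)) != 1) {
    abort("All trial spectra must come from one culture.")
  }
  naive <- vapply(metas, function(m) isTRUE(m$trial_index == 1L), logical(1))
  keep <- which(!naive)
  if (length(keep) == 0) abort("All trials are flagged naive; nothing to average.")
  ref <- spectra[[keep[1]]]
  for (i in keep[-1]) {
    if (!identical(spectra[[i]]$freq_hz, ref$freq_hz) ||
        !identical(spectra[[i]]$channel, ref$channel)) {
      abort("Trial spectra are not on a common channel/frequency grid.")
    }
  }
  pw <- rowMeans(vapply(keep, function(i) spectra[[i]]$power,
                        numeric(nrow(ref))))
  meta <- metas[[keep[1]]]
  meta$trial_index <- NA_integer_
  meta$naive <- NULL
  inact <- sort(unique(unlist(lapply(spectra[keep], attr, "inactive_channels"))))
  new_channel_spectrum(ref$channel, ref$area, ref$freq_hz, pw,
                       stage = stages[1], meta = meta,
                       inactive_channels = inact %||% integer())
}

#' Restrict a channel spectrum to a subset of channels
#'
#' @param cs A `channel_spectrum`.
#' @param channels Channel indices to keep.
#' @return A `channel_spectrum` at the same stage.
#' @export
subset_channels <- function(cs, channels) {
  stopifnot(inherits(cs, "channel_spectrum"))
  out <- filter(as_tibble(cs), .data$channel %in% channels)
  new_channel_spectrum(
    out$channel, out$area, out$freq_hz, out$power,
    stage = spectrum_stage(cs), meta = attr(cs, "meta"),
    inactive_channels = intersect(attr(cs, "inactive_channels") %||% integer(),
                                  channels)
  )
}
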