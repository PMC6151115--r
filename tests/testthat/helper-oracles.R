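# Independent oracles and small fixtures shared across tests.

# Brute-force peak prominence: a literal walk of the definition. From each
# strict local maximum, step left (right) until a sample higher than the
# peak or the signal end; take the minimum over each walked interval;
# prominence is peak height minus the higher of the two minima. Plateaus
# are collapsed to their centre sample. O(n^2), kept deliberately naive.
oracle_prominences <- function(v) {
  n <- length(v)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        idx <- c(idx, i + (j - i) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prom <- numeric(length(idx))
  for (q in seq_along(idx)) {
    p <- idx[q]
    h <- v[p]
    lmin <- h
    j <- p - 1L
    while (j >= 1L && v[j] <= h) {
      if (v[j] < lmin) lmin <- v[j]
      j <- j - 1L
    }
    rmin <- h
    j <- p + 1L
    while (j <= n && v[j] <= h) {
      if (v[j] < rmin) rmin <- v[j]
      j <- j + 1L
    }
    prom[q] <- h - max(lmin, rmin)
  }
  list(index = idx, prominence = prom)
}

# Plain rectangular-window periodogram bandpower of one channel, for
# checking generated oscillations independently of the multitaper pipeline.
oracle_bandpower <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= f_lo & f <= f_hi
  2 * sum(p[sel])
}

# Least-squares slope of log power vs log frequency.
loglog_slope <- function(freq, power, f_lo = 2, f_hi = 400) {
  sel <- freq >= f_lo & freq <= f_hi & power > 0
  unname(coef(lm(log(power[sel]) ~ log(freq[sel])))[2])
}

# A small quick generator config used by unit tests (full 60-channel, 60 s
# study-scale settings are exercised in the acceptance tests).
tiny_config <- function(...) {
  defaults <- list(n_channels = 6L, duration_s = 12, onset_s = 6,
                   rng_seed = 101L)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

tiny_meta <- function(trial_index = 2L, ...) {
  trial_meta("cult_t", trial_index = trial_index, onset_s = 6,
             duration_s = 12, ...)
}

# Normalized single-channel spectrum with unit-sum rows, for detection tests.
flat_spectrum <- function(n_channels = 3, freqs = 1:500, level = NULL) {
  level <- level %||% (1 / length(freqs))
  as_channel_spectrum(
    tibble::tibble(
      channel = rep(seq_len(n_channels), each = length(freqs)),
      freq_hz = rep(freqs, n_channels),
      power = level
    ),
    stage = "normalized"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
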