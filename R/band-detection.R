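# Oscillation-band detection on normalized spectra: prominence-thresholded
# peak detection per channel, active-channel selection, mode-based band
# categorization, and relative peak power against a high-frequency
# reference band.

#' Peaks and prominences of a spectrum vector
#'
#' Finds every strict interior local maximum and computes its prominence:
#' extend a horizontal line left and right from the maximum until the signal
#' rises above the peak height (or the end of the vector is reached), take
#' the minimum of the signal in each of the two intervals, and subtract the
#' higher of the two minima from the peak height. Flat-topped (plateau)
#' maxima are reported once, at the plateau's centre sample.
#'
#' @param values Numeric vector (length >= 3), e.g. one channel's spectrum.
#' @return A tibble with one row per peak: `index`, `height`, `prominence`,
#'   ordered by index.
#' @export
#' @examples
#' peak_prominences(c(1, 3, 2, 4, 1))
peak_prominences <- function(values) {
  res <- peak_prominences_core(values)
  tibble(index = res$index, height = res$height, prominence = res$prominence)
}

# plain-list workhorse behind peak_prominences(), used in the per-channel
# detection loop where tibble construction would dominate
peak_prominences_core <- function(values) {
  n <- length(values)
  if (n < 3) abort("peak_prominences() needs a vector of length >= 3.")
  if (anyNA(values)) abort("`values` must not contain NA.")

  # plateau-aware local maxima via run-length compression
  r <- rle(values)
  nr <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  peak_idx <- integer(0)
  if (nr >= 3) {
    j <- 2:(nr - 1)
    is_pk <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
    pk <- j[is_pk]
    # centre of the plateau (lower-middle sample for even lengths)
    peak_idx <- run_start[pk] + (r$lengths[pk] - 1L) %/% 2L
  }
  if (length(peak_idx) == 0) {
    return(list(index = integer(0), height = numeric(0),
                prominence = numeric(0)))
  }

  prom <- vapply(peak_idx, function(i) {
    h <- values[i]
    higher_left <- which(values[seq_len(i - 1)] > h)
    lb <- if (length(higher_left)) max(higher_left) else 0L
    left_min <- min(values[(lb + 1L):(i - 1L)])
    higher_right <- which(values[(i + 1L):n] > h)
    rb <- if (length(higher_right)) i + min(higher_right) else n + 1L
    right_min <- min(values[(i + 1L):(rb - 1L)])
    h - max(left_min, right_min)
  }, numeric(1))

  list(index = peak_idx, height = values[peak_idx], prominence = prom)
}

#' Detect an oscillation band in a normalized spectrum
#'
#' Per channel, peaks of the full normalized spectrum are ranked by
#' prominence and the highest-prominence peak whose frequency falls inside
#' `search_range` is retained. Channels whose best peak reaches the
#' prominence threshold are "active". The band's mode frequency is the mode
#' of the active channels' peak frequencies (ties broken toward the lowest
#' frequency), and the band label is the canonical range containing that
#' mode.
#'
#' `search_range` is half-open `[lo, hi)` to match the canonical band
#' partition; a range ending at 100 Hz includes 100 Hz.
#'
#' @param cs A `channel_spectrum` at stage `"normalized"`.
#' @param search_range Length-2 numeric, Hz.
#' @param threshold Prominence threshold in normalized units (default
#'   0.001).
#' @return A one-row tibble of class `band_detection`: `band`, `fmin`,
#'   `fmax`, `present`, `n_active`, `mode_freq`, `active_channels`
#'   (list-column), `peaks` (list-column of per-active-channel peak
#'   tibbles).
#' @export
detect_band <- function(cs, search_range, threshold = 0.001) {
  check_stage(cs, "normalized", "detect_band")
  scan_ranges(cs, matrix(search_range, nrow = 1), threshold)
}

#' Scan the four canonical bands
#'
#' Runs the [detect_band()] logic over delta (1-4), theta (4-10), beta
#' (10-30) and gamma (30-100 Hz) and stacks the results; each band is
#' independently present or absent. Per-channel peaks are computed once and
#' shared across the four ranges.
#'
#' @inheritParams detect_band
#' @param bands A band-range tibble as from [band_ranges()].
#' @return A four-row `band_detection` tibble.
#' @export
scan_bands <- function(cs, threshold = 0.001, bands = band_ranges()) {
  check_stage(cs, "normalized", "scan_bands")
  out <- scan_ranges(cs, cbind(bands$fmin, bands$fmax), threshold)
  for (i in seq_len(nrow(out))) {
    if (!out$present[i]) out$band[i] <- bands$band[i]
  }
  out
}

# shared engine: per channel, find all peaks once; per range, keep each
# channel's highest-prominence peak inside the range and summarise
scan_ranges <- function(cs, ranges, threshold) {
  m <- cs_matrix(cs)
  if (any(ranges[, 1] >= ranges[, 2])) {
    abort("`search_range` must be an increasing length-2 frequency pair.")
  }
  if (min(ranges) < min(m$freqs) - 1e-9 || max(ranges) > max(m$freqs) + 1e-9) {
    abort("`search_range` must lie within the spectrum's frequency grid.")
  }
  inactive <- attr(cs, "inactive_channels") %||% integer()
  nch <- length(m$channels)
  peaks_by_channel <- vector("list", nch)
  for (ci in seq_len(nch)) {
    if (m$channels[ci] %in% inactive) next
    pk <- peak_prominences_core(m$P[, ci])
    if (length(pk$index)) {
      pk$freq <- m$freqs[pk$index]
      peaks_by_channel[[ci]] <- pk
    }
  }

  rows <- lapply(seq_len(nrow(ranges)), function(ri) {
    lo <- ranges[ri, 1]; hi <- ranges[ri, 2]
    hi_closed <- abs(hi - 100) < 1e-9
    ch_v <- integer(0); fr_v <- ht_v <- pr_v <- numeric(0)
    for (ci in seq_len(nch)) {
      pk <- peaks_by_channel[[ci]]
      if (is.null(pk)) next
      inside <- which(pk$freq >= lo - 1e-9 &
                        (pk$freq < hi - 1e-9 |
                           (hi_closed & abs(pk$freq - hi) < 1e-9)))
      if (length(inside) == 0) next
      # best peak: highest prominence, ties toward the lower frequency
      best <- inside[order(-pk$prominence[inside], pk$freq[inside])[1]]
      if (pk$prominence[best] >= threshold) {
        ch_v <- c(ch_v, m$channels[ci])
        fr_v <- c(fr_v, pk$freq[best])
        ht_v <- c(ht_v, pk$height[best])
        pr_v <- c(pr_v, pk$prominence[best])
      }
    }
    present <- length(ch_v) > 0
    mode_freq <- if (present) {
      tab <- table(fr_v)
      min(as.numeric(names(tab)[tab == max(tab)])) # tie -> lowest frequency
    } else NA_real_
    band <- if (present) band_of(mode_freq) else band_of(mean(c(lo, hi)))
    tibble(
      band = band, fmin = lo, fmax = hi,
      present = present, n_active = length(ch_v), mode_freq = mode_freq,
      active_channels = list(ch_v),
      peaks = list(tibble(channel = ch_v, freq = fr_v, height = ht_v,
                          prominence = pr_v))
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("band_detection", class(tibble()))
  out
}

#' Relative peak power against a high-frequency reference band
#'
#' For each active channel of a detection, the power at that channel's peak
#' frequency is divided by the mean power over the reference band (200-250
#' Hz by default, endpoints inclusive on the grid), controlling for broadband
#' power differences. The band-level summary is the mean over active
#' channels.
#'
#' Power is taken from a 1/f-corrected (or notch-interpolated) spectrum, not
#' the normalized one, so the ratio is a genuine power contrast.
#'
#' @param cs A `channel_spectrum` at stage `"f_corrected"` or
#'   `"notch_interpolated"`.
#' @param det A one-band `band_detection` row with `present = TRUE`.
#' @param ref_band Length-2 numeric, Hz (default `c(200, 250)`).
#' @return A list with `per_channel` (tibble: `channel`, `peak_freq`,
#'   `rel_power`) and `band_mean` (scalar).
#' @export
relative_peak_power <- function(cs, det, ref_band = c(200, 250)) {
  check_stage(cs, c("f_corrected", "notch_interpolated"),
              "relative_peak_power")
  if (nrow(det) != 1) abort("`det` must be a single band-detection row.")
  if (!isTRUE(det$present)) {
    abort("relative_peak_power() needs a detection with present = TRUE.")
  }
  m <- cs_matrix(cs)
  ref_idx <- which(m$freqs >= ref_band[1] - 1e-9 &
                     m$freqs <= ref_band[2] + 1e-9)
  if (length(ref_idx) == 0) {
    abort("`ref_band` contains no grid frequencies.")
  }
  peaks <- det$peaks[[1]]
  per <- lapply(seq_len(nrow(peaks)), function(i) {
    ci <- match(peaks$channel[i], m$channels)
    ref_mean <- mean(m$P[ref_idx, ci])
    if (ref_mean <= 0) {
      abort(sprintf("Zero reference power on channel %d: cannot divide.",
                    peaks$channel[i]))
    }
    fi <- which(abs(m$freqs - peaks$freq[i]) < 1e-9)
    tibble(channel = peaks$channel[i], peak_freq = peaks$freq[i],
           rel_power = m$P[fi, ci] / ref_mean)
  })
  per <- list_rbind(per)
  list(per_channel = per, band_mean = mean(per$rel_power))
}
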