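#' Multichannel MEA recording container
#'
#' A light container for one trial of a multichannel extracellular recording:
#' a channels x samples voltage matrix, its sampling rate, the per-channel
#' hippocampal-area labels, and the trial metadata.
#'
#' @param signal Numeric matrix, channels x samples (microvolt scale).
#' @param fs Sampling rate in Hz.
#' @param channel_area Character vector, one label per channel, each one of
#'   `"DG"`, `"CA3"`, `"CA1"`, `"off_tissue"`.
#' @param meta A [trial_meta()] list.
#' @param t_start Time (s) of the first sample relative to trial onset
#'   (default 0; non-zero for recordings trimmed with [trim_recording()]).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(signal, fs, channel_area, meta, t_start = 0) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric channels x samples matrix.")
  }
  if (length(channel_area) != nrow(signal)) {
    abort(sprintf(
      "`channel_area` has %d labels but `signal` has %d channels.",
      length(channel_area), nrow(signal)
    ))
  }
  bad <- setdiff(unique(channel_area), c("DG", "CA3", "CA1", "off_tissue"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown area label(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  structure(
    list(
      signal = signal,
      fs = fs,
      channel_area = as.character(channel_area),
      meta = meta,
      t_start = t_start
    ),
    class = "mea_recording"
  )
}

#' Trim a recording to the segment starting at a given time
#'
#' Drops samples before `from_s`; the returned recording remembers its
#' offset (`t_start`), so window times in downstream spectrograms stay on
#' the trial clock. Trimming to the stimulus onset before the spectrogram
#' yields exactly the post-onset analysis windows of the full trial.
#'
#' @param rec An [mea_recording()].
#' @param from_s Trial time (s) of the first retained sample.
#' @return The trimmed [mea_recording()].
#' @export
trim_recording <- function(rec, from_s) {
  stopifnot(inherits(rec, "mea_recording"))
  first <- as.integer(round((from_s - rec$t_start) * rec$fs)) + 1L
  if (first < 1L || first > n_samples(rec)) {
    abort("`from_s` lies outside the recording.")
  }
  out <- mea_recording(rec$signal[, first:n_samples(rec), drop = FALSE],
                       rec$fs, rec$channel_area, rec$meta,
                       t_start = rec$t_start + (first - 1L) / rec$fs)
  attr(out, "band_presence") <- attr(rec, "band_presence")
  attr(out, "active_channels") <- attr(rec, "active_channels")
  out
}

#' Trial metadata
#'
#' Metadata attached to one 60 s trial: culture identity, trial index within
#' the culture (index 1 is the carbachol-naive trial and is discarded from
#' analysis), genotype, days in vitro, and the stimulus timing.
#'
#' @param culture_id Culture identifier (string).
#' @param trial_index Integer 1-6; 1 flags the discarded naive trial.
#' @param genotype `"WT"` or `"KO"`.
#' @param div Days in vitro, one of 7, 13, 26 by default (any positive
#'   integer is accepted).
#' @param onset_s Stimulus-onset time in seconds (default 30).
#' @param duration_s Trial length in seconds (default 60).
#' @return A list of class `trial_meta`.
#' @export
trial_meta <- function(culture_id, trial_index = 2L, genotype = "WT",
                       div = 7L, onset_s = 30, duration_s = 60) {
  if (!genotype %in% c("WT", "KO")) {
    abort("`genotype` must be \"WT\" or \"KO\".")
  }
  if (!(onset_s > 0 && onset_s < duration_s)) {
    abort("`onset_s` must lie strictly inside (0, duration_s).")
  }
  structure(
    list(
      culture_id = as.character(culture_id),
      trial_index = as.integer(trial_index),
      genotype = genotype,
      div = as.integer(div),
      onset_s = onset_s,
      duration_s = duration_s,
      naive = as.integer(trial_index) == 1L
    ),
    class = "trial_meta"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs
  ))
  cat(sprintf(
    "  culture %s, trial %d%s, %s, DIV %d, onset %g s\n",
    x$meta$culture_id, x$meta$trial_index,
    if (isTRUE(x$meta$naive)) " (naive)" else "",
    x$meta$genotype, x$meta$div, x$meta$onset_s
  ))
  areas <- table(x$channel_area)
  cat("  areas:", paste(sprintf("%s=%d", names(areas), areas), collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$signal)
n_samples <- function(rec) ncol(rec$signal)
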