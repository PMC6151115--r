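# Preprocessing: integer-factor decimation behind a zero-phase anti-alias
# low-pass, then a Butterworth high-pass. Both stages are linear and
# length-preserving (reflect padding absorbs filter transients).

#' Preprocessing configuration
#'
#' @param target_fs Target sampling rate in Hz (default 1000). Must divide
#'   the input rate.
#' @param highpass_cutoff High-pass cutoff in Hz (default 1).
#' @param filter_order Butterworth order (default 4).
#' @param zero_phase Apply the high-pass forward-backward (default `TRUE`),
#'   giving zero net phase shift and a squared magnitude response.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 1000, highpass_cutoff = 1,
                              filter_order = 4L, zero_phase = TRUE) {
  if (highpass_cutoff >= target_fs / 2) {
    abort("`highpass_cutoff` must be below the target Nyquist frequency.")
  }
  structure(
    list(target_fs = target_fs, highpass_cutoff = highpass_cutoff,
         filter_order = as.integer(filter_order), zero_phase = zero_phase),
    class = "preprocess_config"
  )
}

# Reflect-pad a vector by `pad` samples at each end (no repeated edge sample).
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
}

# Zero-phase frequency-domain low-pass: unit gain below `f_pass`, raised-
# cosine rolloff to zero at `f_stop`. Applied per channel with reflect
# padding so the circular convolution does not wrap trial edges.
fft_lowpass <- function(x, fs, f_pass, f_stop) {
  n0 <- length(x)
  pad <- min(n0 - 1, as.integer(fs)) # one second of padding
  xp <- reflect_pad(x, pad)
  n <- length(xp)
  freqs <- seq(0, n - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # two-sided: distance from DC
  gain <- ifelse(freqs <= f_pass, 1,
                 ifelse(freqs >= f_stop, 0,
                        0.5 * (1 + cos(pi * (freqs - f_pass) / (f_stop - f_pass)))))
  y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / n
  y[(pad + 1):(pad + n0)]
}

#' Downsample a recording to a target rate
#'
#' Applies a zero-phase anti-aliasing low-pass (flat to 0.40 x target rate,
#' raised-cosine rolloff reaching zero at 0.45 x target rate) and decimates
#' by the integer factor `fs / target_fs`. A recording already at the target
#' rate is returned unchanged.
#'
#' @param rec An [mea_recording()].
#' @param target_fs Target sampling rate in Hz (default 1000).
#' @return An [mea_recording()] at `target_fs` with
#'   `floor(n_samples * target_fs / fs)` samples; metadata and area map are
#'   preserved.
#' @export
downsample <- function(rec, target_fs = 1000) {
  stopifnot(inherits(rec, "mea_recording"))
  if (rec$fs == target_fs) return(rec)
  if (rec$fs < target_fs) {
    abort("Cannot downsample: recording rate is below the target rate.")
  }
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf(
      "Non-integer decimation factor %.6g (fs %g Hz -> %g Hz).",
      factor, rec$fs, target_fs
    ))
  }
  factor <- as.integer(round(factor))
  n_in <- n_samples(rec)
  n_out <- floor(n_in * target_fs / rec$fs)
  keep <- seq(1L, by = factor, length.out = n_out)
  out <- matrix(0, nrow = n_channels(rec), ncol = n_out)
  for (ch in seq_len(n_channels(rec))) {
    filtered <- fft_lowpass(rec$signal[ch, ], rec$fs,
                            f_pass = 0.40 * target_fs,
                            f_stop = 0.45 * target_fs)
    out[ch, ] <- filtered[keep]
  }
  rec2 <- mea_recording(out, target_fs, rec$channel_area, rec$meta,
                        t_start = rec$t_start)
  attr(rec2, "band_presence") <- attr(rec, "band_presence")
  attr(rec2, "active_channels") <- attr(rec, "active_channels")
  rec2
}

# Apply an IIR filter causally with reflect padding of `pad_s` seconds.
apply_iir <- function(x, filt, fs, pad_s) {
  n0 <- length(x)
  pad <- min(n0 - 1, as.integer(round(pad_s * fs)))
  xp <- reflect_pad(x, pad)
  y <- as.numeric(signal::filter(filt, xp))
  y[(pad + 1):(pad + n0)]
}

# Squared magnitude response |H(e^{iw})|^2 of an IIR filter on the n-point
# DFT grid: the exact zero-phase (forward-backward) transfer function.
iir_gain_sq <- function(filt, n) {
  num <- fft(c(filt$b, rep(0, n - length(filt$b))))
  den <- fft(c(filt$a, rep(0, n - length(filt$a))))
  Mod(num / den)^2
}

#' Butterworth high-pass filter a recording
#'
#' Applies the configured Butterworth high-pass to every channel, removing
#' the DC offset and slow drift. With `zero_phase = TRUE` (default) the
#' filter is applied with zero net phase shift and its magnitude response
#' squared (the forward-backward transfer function), realised exactly by
#' multiplying each channel's spectrum with `|H|^2` under reflect padding;
#' with `zero_phase = FALSE` a single causal pass is run in the time
#' domain.
#'
#' @param rec An [mea_recording()] already at the target rate.
#' @param cfg A [preprocess_config()].
#' @return The filtered [mea_recording()].
#' @export
highpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "mea_recording"))
  if (cfg$highpass_cutoff >= rec$fs / 2) {
    abort("High-pass cutoff is at or above the Nyquist frequency.")
  }
  bf <- signal::butter(cfg$filter_order, cfg$highpass_cutoff / (rec$fs / 2),
                       type = "high")
  pad_s <- 10 / cfg$highpass_cutoff # several filter time constants
  out <- rec$signal
  if (cfg$zero_phase) {
    n0 <- n_samples(rec)
    pad <- min(n0 - 1, as.integer(round(pad_s * rec$fs)))
    G <- iir_gain_sq(bf, n0 + 2 * pad)
    for (ch in seq_len(n_channels(rec))) {
      xp <- reflect_pad(rec$signal[ch, ], pad)
      y <- Re(fft(fft(xp) * G, inverse = TRUE)) / length(xp)
      out[ch, ] <- y[(pad + 1):(pad + n0)]
    }
  } else {
    for (ch in seq_len(n_channels(rec))) {
      out[ch, ] <- apply_iir(rec$signal[ch, ], bf, rec$fs, pad_s)
    }
  }
  rec2 <- mea_recording(out, rec$fs, rec$channel_area, rec$meta,
                        t_start = rec$t_start)
  attr(rec2, "band_presence") <- attr(rec, "band_presence")
  attr(rec2, "active_channels") <- attr(rec, "active_channels")
  rec2
}

#' Full preprocessing chain
#'
#' Downsamples to the target rate when needed, then high-pass filters.
#'
#' @inheritParams highpass
#' @return The preprocessed [mea_recording()].
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  if (rec$fs > cfg$target_fs) rec <- downsample(rec, cfg$target_fs)
  highpass(rec, cfg)
}

#' Closed-form Butterworth high-pass magnitude response
#'
#' `|H(f)|^2 = 1 / (1 + (fc / f)^(2 n))` for a high-pass of order `n` and
#' cutoff `fc`; the amplitude response of one pass is its square root, and a
#' forward-backward (zero-phase) application attenuates by `|H|^2`.
#'
#' @param f Frequency in Hz (vectorised).
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order.
#' @param zero_phase If `TRUE`, return the two-pass amplitude response.
#' @return Amplitude ratio in `[0, 1]`.
#' @export
butterworth_highpass_response <- function(f, cutoff = 1, order = 4,
                                          zero_phase = TRUE) {
  hsq <- 1 / (1 + (cutoff / f)^(2 * order))
  if (zero_phase) hsq else sqrt(hsq)
}
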