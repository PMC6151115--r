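# Recording container I/O: a samples x channels signal CSV plus a JSON
# sidecar holding the sampling rate, area map and trial metadata. Doubles
# are serialized with 17 significant digits so the round trip is bit-exact.

#' Write a recording to a CSV + JSON container
#'
#' Writes `<prefix>.signal.csv` (samples x channels, header `ch_001`, ...)
#' and `<prefix>.json` (fs, channel_area, trial metadata). The signal is
#' written with 17 significant digits, so reading it back reproduces the
#' matrix bit-exactly.
#'
#' @param rec An [mea_recording()].
#' @param prefix Output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "mea_recording"))
  nc <- n_channels(rec)
  header <- paste(sprintf("ch_%03d", seq_len(nc)), collapse = ",")
  cols <- lapply(seq_len(nc), function(ch) sprintf("%.17g", rec$signal[ch, ]))
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(header, lines), paste0(prefix, ".signal.csv"))
  side <- list(
    fs = rec$fs,
    channel_area = rec$channel_area,
    meta = unclass(rec$meta)
  )
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording from a CSV + JSON container
#'
#' @param prefix Path prefix as used by [write_recording()].
#' @return An [mea_recording()].
#' @export
read_recording <- function(prefix) {
  sig_path <- paste0(prefix, ".signal.csv")
  meta_path <- paste0(prefix, ".json")
  for (p in c(sig_path, meta_path)) {
    if (!file.exists(p)) abort(sprintf("Missing container file: %s", p))
  }
  side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "channel_area", "meta")) {
    if (is.null(side[[field]])) {
      abort(sprintf("Recording container is missing field `%s` in %s.",
                    field, meta_path))
    }
  }
  for (field in c("culture_id", "trial_index", "genotype", "div",
                  "onset_s", "duration_s")) {
    if (is.null(side$meta[[field]])) {
      abort(sprintf("Recording metadata is missing field `%s`.", field))
    }
  }
  tab <- utils::read.csv(sig_path, header = TRUE,
                         colClasses = "numeric", check.names = FALSE)
  sig <- t(as.matrix(tab))
  dimnames(sig) <- NULL
  meta <- trial_meta(
    culture_id = side$meta$culture_id,
    trial_index = side$meta$trial_index,
    genotype = side$meta$genotype,
    div = side$meta$div,
    onset_s = as.numeric(side$meta$onset_s),
    duration_s = as.numeric(side$meta$duration_s)
  )
  mea_recording(sig, as.numeric(side$fs), side$channel_area, meta)
}
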