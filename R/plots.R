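# ggplot2 graphics: spectra overlays, band-detection summaries, fitted
# occurrence curves, and AIC ranking plots.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline facet_wrap labs scale_x_log10 scale_y_log10 theme_minimal
#'   position_dodge geom_errorbar
#' @export
ggplot2::autoplot

#' Plot a channel spectrum
#'
#' Overlays every channel's spectrum (the display used to judge which peaks
#' are shared across channels), optionally faceted by hippocampal area.
#'
#' @param object A `channel_spectrum`.
#' @param facet_area Facet by area (default `TRUE`).
#' @param log_power Log-scale the power axis (default `FALSE`; normalized
#'   spectra are usually viewed linearly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_spectrum <- function(object, facet_area = TRUE,
                                      log_power = FALSE, ...) {
  p <- ggplot(as_tibble(object),
              aes(x = .data$freq_hz, y = .data$power,
                  group = .data$channel)) +
    geom_line(alpha = 0.4, linewidth = 0.3) +
    labs(
      x = "Frequency (Hz)",
      y = sprintf("Power (%s)", spectrum_stage(object)),
      title = sprintf("Per-channel spectrum (stage: %s)",
                      spectrum_stage(object))
    ) +
    theme_minimal()
  if (facet_area) p <- p + facet_wrap(~area)
  if (log_power) p <- p + scale_y_log10()
  p
}

#' Plot a band-detection result
#'
#' Active-channel counts per band, with the mode peak frequency labelled.
#'
#' @param object A `band_detection` tibble from [scan_bands()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_detection <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(label = ifelse(.data$present,
                          sprintf("%g Hz", .data$mode_freq), "absent"))
  ggplot(df, aes(x = .data$band, y = .data$n_active,
                 fill = .data$present)) +
    geom_col() +
    ggplot2::geom_text(aes(label = .data$label), vjust = -0.4, size = 3) +
    labs(x = NULL, y = "Active channels",
         title = "Oscillation-band detection") +
    theme_minimal()
}

#' Plot fitted occurrence probabilities over DIV
#'
#' @param object An `occurrence_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occurrence_fit <- function(object, ...) {
  cells <- fitted_occurrence(object)
  if (!"div" %in% names(cells)) {
    abort("The fit has no DIV term; nothing to plot over DIV.")
  }
  has_geno <- "genotype" %in% names(cells)
  p <- ggplot(cells, aes(x = as.numeric(as.character(.data$div)),
                         y = .data$probability))
  if (has_geno) {
    p <- p + geom_line(aes(colour = .data$genotype)) +
      geom_point(aes(colour = .data$genotype))
  } else {
    p <- p + geom_line() + geom_point()
  }
  p +
    ggplot2::ylim(0, 1) +
    labs(x = "Days in vitro", y = "Occurrence probability",
         title = "Fitted band-occurrence probability") +
    theme_minimal()
}

#' Plot an AIC model ranking
#'
#' @param object A `model_selection` from [select_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_selection <- function(object, ...) {
  df <- mutate(object$ranking,
               formula = factor(.data$formula,
                                levels = rev(.data$formula)))
  ggplot(df, aes(x = .data$delta_aic, y = .data$formula)) +
    geom_point() +
    geom_vline(xintercept = 2, linetype = "dashed") +
    labs(x = expression(Delta * "AIC"), y = NULL,
         title = "Candidate occurrence models") +
    theme_minimal()
}
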