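# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an occurrence fit's coefficients
#'
#' @param x An `occurrence_fit` from [fit_logistic()].
#' @param conf.int Add Wald confidence intervals (default `FALSE`).
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log-odds), `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.occurrence_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p.value = sm[, "Pr(>|z|)"]
  )
  if (x$firth) out$estimate <- unname(x$coefficients)
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' One-row summary of an occurrence fit
#'
#' @param x An `occurrence_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `k`, `logLik`, `AIC`, `converged`,
#'   `separation`.
#' @export
glance.occurrence_fit <- function(x, ...) {
  tibble(
    n = x$n, k = x$k, logLik = x$log_likelihood, AIC = x$aic,
    converged = x$converged, separation = x$separation
  )
}

#' Tidy a model selection: the AIC ranking table
#'
#' @param x A `model_selection` from [select_model()].
#' @param ... Unused.
#' @return The ranking tibble (`formula`, `k`, `log_lik`, `aic`,
#'   `delta_aic`, `converged`).
#' @export
tidy.model_selection <- function(x, ...) x$ranking

#' One-row summary of a model selection
#'
#' @param x A `model_selection`.
#' @param ... Unused.
#' @return A tibble with the winning formula, its AIC, the number of
#'   candidates, and the likelihood-ratio p-value against the null model.
#' @export
glance.model_selection <- function(x, ...) {
  tibble(
    best_formula = x$ranking$formula[1],
    aic = x$ranking$aic[1],
    n_candidates = nrow(x$ranking),
    lrt_p_vs_null = x$lrt_p
  )
}

#' Predicted occurrence probabilities per design cell
#'
#' @param x An `occurrence_fit`.
#' @return A tibble of the distinct predictor combinations in the fitting
#'   data with their fitted occurrence probabilities.
#' @export
fitted_occurrence <- function(x) {
  stopifnot(inherits(x, "occurrence_fit"))
  mf <- x$fit$model
  preds <- setdiff(names(mf), "present")
  if (length(preds) == 0) {
    return(tibble(probability = unique(stats::fitted(x$fit))))
  }
  cells <- distinct(as_tibble(mf[preds]))
  cells$probability <- as.numeric(
    stats::predict(x$fit, newdata = cells, type = "response")
  )
  cells
}
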