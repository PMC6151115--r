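# Occurrence statistics: per-culture presence/absence of each oscillation
# band modelled by binomial logistic regression over genotype, DIV and area,
# with AIC model selection over the marginality-respecting model lattice,
# plus two-way ANOVA group comparisons for peak frequency and peak power.

prepare_occurrence_data <- function(tab) {
  df <- as_tibble(tab)
  if (!"present" %in% names(df)) abort("Occurrence table needs a `present` column.")
  df$present <- as.integer(df$present)
  if (!all(df$present %in% c(0L, 1L))) abort("`present` must be binary.")
  if ("genotype" %in% names(df) && !is.factor(df$genotype)) {
    df$genotype <- factor(df$genotype, levels = c("WT", "KO"))
  }
  if ("div" %in% names(df) && !is.factor(df$div)) {
    df$div <- factor(df$div, levels = sort(unique(as.numeric(df$div))))
  }
  if ("area" %in% names(df) && !is.factor(df$area)) {
    df$area <- factor(df$area, levels = intersect(c("DG", "CA3", "CA1"),
                                                  unique(df$area)))
  }
  df
}

#' Collapse per-area occurrence rows to one row per culture
#'
#' A culture counts as expressing a band if at least one of its areas is
#' active in that band (logical OR over areas).
#'
#' @param tab Occurrence tibble with one row per culture x area x band
#'   (columns `culture_id`, `genotype`, `div`, `area`, `band`, `present`).
#' @return A tibble with one row per culture x band and no `area` column.
#' @export
collapse_areas <- function(tab) {
  df <- as_tibble(tab)
  need <- c("culture_id", "area", "band", "present")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  dup <- df |>
    dplyr::count(.data$culture_id, .data$area, .data$band) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort("Duplicate culture x area x band rows in the occurrence table.")
  }
  grp <- intersect(c("culture_id", "genotype", "div", "band"), names(df))
  df |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(present = as.integer(any(.data$present > 0)), .groups = "drop")
}

# ---- logistic fits ----------------------------------------------------------

#' Binomial logistic fit of band occurrence
#'
#' Maximum-likelihood logistic regression of per-culture (or per-area)
#' presence on any of genotype, DIV and area; DIV enters as a categorical
#' factor by default. Non-convergence and complete/quasi-complete
#' separation are flagged on the returned object rather than silently
#' ignored; `firth = TRUE` refits with a Firth-style penalized score
#' adjustment that keeps estimates finite under separation.
#'
#' @param tab Occurrence tibble with a binary `present` column and the
#'   predictors named in `formula`.
#' @param formula Model formula, e.g. `present ~ genotype + div`.
#' @param div_coding `"categorical"` (default) or `"numeric"`.
#' @param firth Use the Firth-style penalized fit (default `FALSE`).
#' @return An object of class `occurrence_fit` with elements `fit`,
#'   `formula`, `coefficients`, `log_likelihood`, `aic`, `n`, `converged`,
#'   `separation`.
#' @export
fit_logistic <- function(tab, formula = present ~ genotype + div,
                         div_coding = c("categorical", "numeric"),
                         firth = FALSE) {
  div_coding <- match.arg(div_coding)
  df <- prepare_occurrence_data(tab)
  if (nrow(df) == 0) abort("Empty occurrence table.")
  if (div_coding == "numeric" && "div" %in% names(df)) {
    df$div <- as.numeric(as.character(df$div))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(formula, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # quasi/complete separation can converge without any glm warning: flag
  # fits whose log-odds run away or whose fitted values hit 0/1
  est <- coef(fit)[!is.na(coef(fit))]
  if (max(abs(est)) > 10 ||
      any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)) {
    separation <- TRUE
  }
  converged <- fit$converged && !separation
  if (firth && separation) {
    ff <- firth_logistic(stats::model.matrix(fit), fit$y)
    fit$coefficients <- ff$beta
    ll <- ff$log_likelihood
    converged <- ff$converged
  } else {
    ll <- as.numeric(logLik(fit))
  }
  k <- length(coef(fit))
  structure(
    list(
      fit = fit, formula = formula,
      coefficients = coef(fit),
      log_likelihood = ll,
      aic = 2 * k - 2 * ll,
      n = nrow(df),
      k = k,
      converged = converged,
      separation = separation,
      firth = firth && separation
    ),
    class = "occurrence_fit"
  )
}

# Firth-style penalized logistic regression: IWLS with the score adjusted by
# the hat values, so estimates stay finite under separation.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X, X * W)
    # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
    h <- rowSums((X %*% solve(XtWX)) * X) * W
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- as.vector(solve(XtWX, U))
    # damp large Newton steps: the penalized likelihood is well-behaved but
    # early steps from beta = 0 can overshoot under separation
    if (max(abs(step)) > 1) step <- step / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- as.vector(X %*% beta)
  p <- plogis(eta)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  list(beta = stats::setNames(as.vector(beta), colnames(X)),
       log_likelihood = ll, converged = converged)
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("<occurrence_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AIC = %.3f%s%s\n",
              x$n, x$k, x$log_likelihood, x$aic,
              if (!x$converged) ", NOT converged" else "",
              if (x$separation) ", separation detected" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

# ---- candidate models and AIC selection -------------------------------------

#' Candidate model formulas over the occurrence predictors
#'
#' Enumerates every model from the null (intercept-only) to the full
#' factorial that respects marginality: an interaction appears only together
#' with all its lower-order terms.
#'
#' @param predictors Character vector of predictor names (default
#'   `c("genotype", "div", "area")`).
#' @param response Response name (default `"present"`).
#' @return A list of formulas, the null model first.
#' @export
candidate_formulas <- function(predictors = c("genotype", "div", "area"),
                               response = "present") {
  p <- length(predictors)
  all_terms <- character(0)
  term_parts <- list()
  for (ord in seq_len(p)) {
    combs <- utils::combn(predictors, ord, simplify = FALSE)
    for (cc in combs) {
      all_terms <- c(all_terms, paste(cc, collapse = ":"))
      term_parts <- c(term_parts, list(cc))
    }
  }
  nt <- length(all_terms)
  keep <- list(character(0)) # null model
  for (mask in seq_len(2^nt - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nt) - 1)) > 0)
    ok <- TRUE
    for (s in sel) {
      parts <- term_parts[[s]]
      if (length(parts) > 1) {
        subs <- unlist(lapply(seq_len(length(parts) - 1), function(o) {
          vapply(utils::combn(parts, o, simplify = FALSE),
                 paste, character(1), collapse = ":")
        }))
        # marginality: every lower-order term of an interaction is included
        if (!all(subs %in% all_terms[sel])) { ok <- FALSE; break }
      }
    }
    if (ok) keep <- c(keep, list(all_terms[sel]))
  }
  lapply(keep, function(tt) {
    rhs <- if (length(tt) == 0) "1" else paste(tt, collapse = " + ")
    as.formula(paste(response, "~", rhs))
  })
}

#' AIC model selection over candidate logistic models
#'
#' Fits every candidate formula, ranks by AIC (ties broken toward fewer
#' parameters), and reports the likelihood-ratio test of the winning model
#' against the null model. Candidates that fail to fit are excluded with a
#' warning.
#'
#' @param tab Occurrence tibble.
#' @param formulas List of candidate formulas; by default all
#'   marginality-respecting models over the predictors present in `tab`
#'   (among genotype, div, area), including the null model.
#' @param ... Passed to [fit_logistic()].
#' @return An object of class `model_selection`: list with `best`
#'   (an `occurrence_fit`), `ranking` (tibble), `fits` (named list), and
#'   `lrt_p` (best vs null).
#' @export
select_model <- function(tab, formulas = NULL, ...) {
  df <- prepare_occurrence_data(tab)
  if (is.null(formulas)) {
    preds <- intersect(c("genotype", "div", "area"), names(df))
    preds <- preds[vapply(preds, function(p) length(unique(df[[p]])) > 1,
                          logical(1))]
    formulas <- candidate_formulas(preds)
  }
  if (length(formulas) < 2) abort("Need at least two candidate models.")
  labels <- vapply(formulas, function(f) deparse1(f[[3]]), character(1))
  fits <- vector("list", length(formulas))
  ok <- logical(length(formulas))
  for (i in seq_along(formulas)) {
    res <- tryCatch(fit_logistic(df, formulas[[i]], ...), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("Candidate `%s` failed: %s", labels[i], conditionMessage(res)))
    } else {
      fits[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (!any(labels[ok] == "1")) abort("The null model must be among the candidates.")
  fits <- fits[ok]; labels <- labels[ok]
  ranking <- tibble(
    formula = labels,
    k = vapply(fits, function(f) f$k, numeric(1)),
    log_lik = vapply(fits, function(f) f$log_likelihood, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  ord <- order(ranking$aic, ranking$k)
  ranking <- ranking[ord, ]
  ranking$delta_aic <- ranking$aic - ranking$aic[1]
  fits <- fits[ord]
  names(fits) <- ranking$formula
  best <- fits[[1]]
  null_fit <- fits[[which(ranking$formula == "1")]]
  lrt_p <- if (best$k > null_fit$k) {
    pchisq(2 * (best$log_likelihood - null_fit$log_likelihood),
           df = best$k - null_fit$k, lower.tail = FALSE)
  } else 1
  structure(
    list(best = best, ranking = ranking, fits = fits, lrt_p = lrt_p),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> best: present ~", x$ranking$formula[1],
      sprintf(" (AIC %.2f, LRT vs null p = %.4g)\n", x$ranking$aic[1], x$lrt_p))
  print(x$ranking)
  invisible(x)
}

# ---- group comparisons ------------------------------------------------------

#' Two-way ANOVA of a per-culture measure over genotype and DIV
#'
#' Fixed-effects two-way ANOVA (main effects and, when every genotype x DIV
#' cell is populated, their interaction) with Type II sums of squares, for
#' per-culture peak frequency or relative peak power. Significance is
#' flagged at the family-wise level `alpha` (default 0.0125, i.e. 0.05
#' split over a family of four band-wise tests).
#'
#' @param data Data frame with the response column and factors `genotype`
#'   and `div`.
#' @param response Name of the response column (default `"value"`).
#' @param alpha Per-test significance level (default 0.0125).
#' @return A tibble of class `band_anova`: `term`, `sumsq`, `df`,
#'   `statistic`, `p_value`, `significant`; attributes `alpha` and
#'   `df_residual`.
#' @export
compare_groups <- function(data, response = "value", alpha = 0.0125) {
  df <- as_tibble(data)
  if (!response %in% names(df)) {
    abort(sprintf("No column `%s` in `data`.", response))
  }
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  df$genotype <- factor(df$genotype)
  df$div <- factor(df$div, levels = sort(unique(as.numeric(as.character(df$div)))))
  if (nrow(df) < 2 || (length(levels(df$genotype)) < 2 &&
                       length(levels(df$div)) < 2)) {
    abort("Need at least two observations spread over at least two cells.")
  }
  cells <- table(df$genotype, df$div)
  with_inter <- all(cells > 0) && length(levels(df$genotype)) > 1 &&
    length(levels(df$div)) > 1
  if (!with_inter) {
    warn("Empty design cells (or a single-level factor): interaction dropped.")
  }
  rhs <- if (with_inter) "genotype * div" else
    paste(c(if (length(levels(df$genotype)) > 1) "genotype",
            if (length(levels(df$div)) > 1) "div"), collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  fit <- lm(fml, data = df)
  an <- tryCatch(suppressWarnings(car::Anova(fit, type = 2)),
                 error = function(e) NULL)
  if (is.null(an)) {
    # degenerate fit (e.g. zero residual variance): report the model terms
    # with undefined statistics rather than failing
    tl <- attr(terms(fit), "term.labels")
    out <- tibble(term = tl, sumsq = NA_real_, df = NA_real_,
                  statistic = NA_real_, p_value = NA_real_,
                  significant = FALSE)
    return(structure(out, alpha = alpha, df_residual = fit$df.residual,
                     class = c("band_anova", class(tibble()))))
  }
  terms_out <- rownames(an)
  keep <- terms_out != "Residuals"
  out <- tibble(
    term = terms_out[keep],
    sumsq = an$`Sum Sq`[keep],
    df = an$Df[keep],
    statistic = an$`F value`[keep],
    p_value = an$`Pr(>F)`[keep],
    significant = !is.na(an$`Pr(>F)`[keep]) & an$`Pr(>F)`[keep] < alpha
  )
  structure(out, alpha = alpha,
            df_residual = an$Df[!keep],
            class = c("band_anova", class(tibble())))
}
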