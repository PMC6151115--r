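# Occurrence statistics: area collapse, logistic fits, AIC selection and
# the two-way group comparisons.

sim_occurrence <- function(n, p_by_div, seed, genotype_shift = 0) {
  withr::with_seed(seed, {
    g <- expand.grid(div = as.numeric(names(p_by_div)),
                     genotype = c("WT", "KO"), rep = seq_len(n),
                     stringsAsFactors = FALSE)
    eta <- qlogis(p_by_div[as.character(g$div)]) +
      ifelse(g$genotype == "KO", genotype_shift, 0)
    tibble::tibble(
      culture_id = sprintf("c%05d", seq_len(nrow(g))),
      genotype = g$genotype, div = g$div, band = "gamma",
      present = rbinom(nrow(g), 1, plogis(eta))
    )
  })
}

test_that("area collapse is a logical OR over areas", {
  tab <- tibble::tibble(
    culture_id = rep(c("a", "b"), each = 3),
    genotype = "WT", div = 7,
    area = rep(c("DG", "CA3", "CA1"), 2),
    band = "gamma",
    present = c(0, 1, 0, 0, 0, 0)
  )
  out <- collapse_areas(tab)
  expect_equal(out$present[out$culture_id == "a"], 1L)
  expect_equal(out$present[out$culture_id == "b"], 0L)
  expect_false("area" %in% names(out))
  # collapsed rate dominates every per-area rate
  set.seed(2)
  big <- tidyr::expand_grid(culture_id = sprintf("c%03d", 1:50),
                            area = c("DG", "CA3", "CA1"))
  big$genotype <- "WT"; big$div <- 7; big$band <- "beta"
  big$present <- rbinom(nrow(big), 1, 0.3)
  coll <- collapse_areas(big)
  for (a in c("DG", "CA3", "CA1")) {
    expect_gte(mean(coll$present), mean(big$present[big$area == a]))
  }
  expect_error(collapse_areas(dplyr::bind_rows(tab, tab[1, ])), "Duplicate")
})

test_that("intercept-only fit recovers the empirical rate and AIC identity", {
  tab <- tibble::tibble(genotype = "WT", div = 7,
                        present = rep(c(0, 1), 50))
  fit <- fit_logistic(tab, present ~ 1)
  expect_lt(abs(unname(fit$coefficients[1])), 1e-8) # logit(0.5) = 0
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$log_likelihood)
  expect_equal(fit$aic, 2 - 2 * fit$log_likelihood)
  expect_true(fit$converged)
  g <- generics::glance(fit)
  expect_equal(g$AIC, fit$aic)
  expect_error(fit_logistic(tab[0, ], present ~ 1), "Empty")
})

test_that("known logistic coefficients are recovered within 3 SE", {
  p <- c("7" = 0.27, "13" = 0.62, "26" = 0.65)
  tab <- sim_occurrence(350, p, seed = 61) # 2100 observations
  fit <- fit_logistic(tab, present ~ div)
  td <- generics::tidy(fit)
  truth <- c(qlogis(0.27), qlogis(0.62) - qlogis(0.27),
             qlogis(0.65) - qlogis(0.27))
  expect_equal(nrow(td), 3)
  for (i in 1:3) {
    expect_lt(abs(td$estimate[i] - truth[i]), 3 * td$std.error[i])
  }
})

test_that("a saturated fit reproduces the observed cell proportions", {
  tab <- sim_occurrence(40, c("7" = 0.3, "13" = 0.6, "26" = 0.7), seed = 8,
                        genotype_shift = 0.4)
  fit <- fit_logistic(tab, present ~ genotype * div)
  cells <- fitted_occurrence(fit)
  obs <- dplyr::summarise(
    dplyr::group_by(prepare_df <- dplyr::mutate(tab,
                                                div = factor(div),
                                                genotype = factor(genotype,
                                                                  c("WT", "KO"))),
                    genotype, div),
    rate = mean(present), .groups = "drop")
  j <- dplyr::left_join(cells, obs, by = c("genotype", "div"))
  expect_lt(max(abs(j$probability - j$rate)), 1e-6)
})

test_that("complete separation is flagged, Firth fallback stays finite", {
  tab <- tibble::tibble(
    genotype = rep(c("WT", "KO"), each = 20),
    div = 7,
    present = rep(c(0L, 1L), each = 20)
  )
  fit <- fit_logistic(tab, present ~ genotype)
  expect_true(fit$separation)
  expect_false(fit$converged)
  ff <- fit_logistic(tab, present ~ genotype, firth = TRUE)
  expect_true(ff$converged)
  expect_lt(max(abs(ff$coefficients)), 10)
})

test_that("candidate set respects marginality and includes the null model", {
  fl <- candidate_formulas(c("genotype", "div"))
  lbl <- vapply(fl, function(f) deparse1(f[[3]]), character(1))
  expect_true("1" %in% lbl)
  expect_setequal(lbl, c("1", "genotype", "div", "genotype + div",
                         "genotype + div + genotype:div"))
  fl3 <- candidate_formulas(c("genotype", "div", "area"))
  lbl3 <- vapply(fl3, function(f) deparse1(f[[3]]), character(1))
  # no interaction without both mains
  expect_false(any(grepl("genotype:div", lbl3) & !grepl("\\bdiv\\b", lbl3)))
  expect_equal(length(fl3), 19L) # marginality-respecting lattice on 3 factors
})

test_that("AIC selection finds a strong DIV effect and reports the LRT", {
  tab <- sim_occurrence(150, c("7" = 0.27, "13" = 0.62, "26" = 0.65),
                        seed = 303)
  sel <- select_model(tab)
  expect_true(grepl("div", sel$ranking$formula[1]))
  expect_lt(sel$lrt_p, 0.001)
  expect_equal(sel$ranking$delta_aic[1], 0)
  expect_true(all(diff(sel$ranking$aic) >= 0))
  td <- generics::tidy(sel)
  expect_identical(td, sel$ranking)
})

test_that("equal fits rank by parameter count, smaller model first", {
  # perfectly balanced cells: every fitted coefficient is exactly zero, so
  # all three models share one log-likelihood and AIC orders by k alone
  tab <- tidyr::expand_grid(genotype = c("WT", "KO"), div = c(7, 13),
                            rep = 1:10, present = 0:1)
  sel <- select_model(tab, formulas = list(present ~ genotype + div,
                                           present ~ genotype,
                                           present ~ 1))
  expect_equal(sel$ranking$formula[1], "1")
  expect_equal(sel$best$k, 1)
  lls <- sel$ranking$log_lik
  expect_lt(max(lls) - min(lls), 1e-8)
  expect_true(all(diff(sel$ranking$k) >= 0)) # ties broken toward smaller k
  expect_equal(sel$lrt_p, 1) # best model is the null itself
})

test_that("two-way ANOVA flags a large genotype shift at alpha = 0.0125", {
  set.seed(5)
  df <- tidyr::expand_grid(genotype = c("WT", "KO"), div = c(7, 13, 26),
                           rep = 1:12)
  df$value <- rnorm(nrow(df), sd = 0.5) + ifelse(df$genotype == "KO", 4, 0)
  an <- compare_groups(df)
  expect_s3_class(an, "band_anova")
  geno <- an[an$term == "genotype", ]
  expect_true(geno$significant)
  expect_lt(geno$p_value, 0.0125)
  expect_false(an$significant[an$term == "div"])
  expect_equal(attr(an, "alpha"), 0.0125)
})

test_that("degenerate ANOVA inputs are handled, not crashed", {
  df <- tidyr::expand_grid(genotype = c("WT", "KO"), div = c(7, 13), rep = 1:4)
  df$value <- 1 # all identical
  an <- compare_groups(df)
  expect_true(all(!an$significant))
  # empty cell: interaction dropped with a warning
  df2 <- df[!(df$genotype == "KO" & df$div == 13), ]
  df2$value <- rnorm(nrow(df2))
  expect_warning(an2 <- compare_groups(df2), "interaction|cells")
  expect_false(any(grepl(":", an2$term)))
  expect_error(compare_groups(df[1, ]), "at least two")
})

test_that("full-vs-null LRT holds its nominal size under the null", {
  # no true effects: the full-model likelihood-ratio test against the null
  # should reject at about its nominal 5% rate
  n_rej <- 0L
  n_rep <- 400L
  for (r in seq_len(n_rep)) {
    tab <- sim_occurrence(20, c("7" = 0.5, "13" = 0.5, "26" = 0.5),
                          seed = 7000 + r)
    full <- fit_logistic(tab, present ~ genotype * div)
    null <- fit_logistic(tab, present ~ 1)
    lr <- 2 * (full$log_likelihood - null$log_likelihood)
    p <- pchisq(lr, df = full$k - null$k, lower.tail = FALSE)
    if (p < 0.05) n_rej <- n_rej + 1L
  }
  rate <- n_rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 2 * se + 0.01)
})
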