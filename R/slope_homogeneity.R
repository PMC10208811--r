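prep_pooled_data <- function(records) {
  counts <- table(records$group)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 species: ",
            paste(small, collapse = ", "), call. = FALSE)
    records <- records[!(records$group %in% small), , drop = FALSE]
  }
  if (length(unique(records$group)) < 2L) {
    stop("slope-homogeneity comparison needs at least 2 groups with >= 2 ",
         "species each", call. = FALSE)
  }
  tl <- log10_transform(records)
  data.frame(x = tl$x, y = tl$y, group = factor(records$group))
}

# Gaussian log-likelihood with profiled (ML) variance, as used by logLik.lm.
loglik_profiled <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

#' Compare pooled allometric models: one line, common slope, free slopes
#'
#' Fits three nested OLS models to the pooled log10 data: M0, a single
#' regression line ignoring groups; M1, group-specific intercepts with a
#' common slope; M2, group-specific slopes and intercepts. Models are scored
#' by AIC and BIC with the Gaussian log-likelihood at the profiled ML
#' variance (lnL = -(n/2)(ln(2 pi RSS/n) + 1)) and parameter count
#' k = number of regression coefficients + 1 for the variance — the same
#' convention as `stats::logLik`/`BIC` on `lm` fits, so the reported BIC is
#' directly comparable to R's. Ties in BIC (difference below 1e-9) go to the
#' simpler model.
#'
#' Groups with fewer than 2 species are excluded with a warning; if that
#' leaves fewer than 2 groups the comparison is an error.
#'
#' @param records species table with columns `group`, `mass_g`,
#'   `bmr_mlO2_h`.
#' @return An object of class `model_comparison`: a list with `models`
#'   (data frame of k, logLik, RSS, AIC, BIC per model), `best_by_bic`,
#'   `common_slope`, `common_slope_se` (from M1), `n`, and `groups`.
#' @seealso [common_slope()], [ancova_slope_test()]
#' @export
fit_pooled_models <- function(records) {
  d <- prep_pooled_data(records)
  n <- nrow(d)
  m0 <- lm(y ~ x, data = d)
  m1 <- lm(y ~ x + group, data = d)
  m2 <- lm(y ~ x * group, data = d)
  fits <- list(M0 = m0, M1 = m1, M2 = m2)
  rss <- vapply(fits, function(m) sum(resid(m)^2), numeric(1))
  k <- vapply(fits, function(m) length(coef(m)) + 1L, numeric(1))
  ll <- loglik_profiled(rss, n)
  aic <- 2 * k - 2 * ll
  bic <- k * log(n) - 2 * ll
  # tie-break toward the simpler model (ties below 1e-9; robust to RSS = 0,
  # where the profiled likelihood is +Inf and BIC -Inf)
  best <- names(fits)[which(bic <= min(bic) + 1e-9)[1]]
  s1 <- summary(m1)$coefficients
  structure(
    list(
      models = data.frame(model = names(fits), k = k, loglik = ll, rss = rss,
                          aic = aic, bic = bic, row.names = NULL),
      best_by_bic = best,
      common_slope = unname(coef(m1)["x"]),
      common_slope_se = s1["x", 2],
      n = n,
      groups = levels(d$group)
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Pooled allometric models (n = %d, %d groups)\n",
              x$n, length(x$groups)))
  print(x$models, row.names = FALSE, digits = 6)
  cat(sprintf("Best by BIC: %s\nCommon slope (M1): %.4f +/- %.4f\n",
              x$best_by_bic, x$common_slope, x$common_slope_se))
  invisible(x)
}

#' ANCOVA test of slope homogeneity across groups
#'
#' Nested-model F test of the mass-by-group interaction: compares the
#' free-slopes model M2 against the common-slope model M1,
#' F = \[(RSS1 - RSS2)/(df1 - df2)\] / \[RSS2/df2\], with a two-sided p from
#' the F distribution. Rejection indicates the scaling exponent differs
#' among groups.
#'
#' @inheritParams fit_pooled_models
#' @return A list: `F`, `df_num`, `df_den`, `p`.
#' @export
ancova_slope_test <- function(records) {
  d <- prep_pooled_data(records)
  m1 <- lm(y ~ x + group, data = d)
  m2 <- lm(y ~ x * group, data = d)
  rss1 <- sum(resid(m1)^2); df1 <- m1$df.residual
  rss2 <- sum(resid(m2)^2); df2 <- m2$df.residual
  Fstat <- ((rss1 - rss2) / (df1 - df2)) / (rss2 / df2)
  list(F = Fstat, df_num = df1 - df2, df_den = df2,
       p = pf(Fstat, df1 - df2, df2, lower.tail = FALSE))
}

#' Common scaling exponent across groups
#'
#' The shared slope of the common-slope model M1 (group intercepts, one
#' exponent), with its OLS standard error. This is the exponent at which
#' clade intercepts are renormalized before forming BMR ratios.
#'
#' @inheritParams fit_pooled_models
#' @return A list: `slope`, `se`.
#' @export
common_slope <- function(records) {
  mc <- fit_pooled_models(records)
  list(slope = mc$common_slope, se = mc$common_slope_se)
}
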