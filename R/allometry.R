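#' Log10-transform a species table into regression vectors
#'
#' The allometric model BMR = a * m^b is linear on the log10 scale:
#' log10(BMR) = log10(a) + b * log10(m). This helper produces the paired
#' regression vectors, preserving row order.
#'
#' @param records species table as returned by [read_species_table()] (needs
#'   columns `mass_g` and `bmr_mlO2_h`).
#' @return A list with numeric vectors `x` (log10 mass) and `y` (log10 BMR).
#' @export
log10_transform <- function(records) {
  m <- records$mass_g
  b <- records$bmr_mlO2_h
  if (any(!is.finite(m)) || any(m <= 0) || any(!is.finite(b)) || any(b <= 0)) {
    stop("log10_transform requires strictly positive mass and BMR",
         call. = FALSE)
  }
  list(x = log10(m), y = log10(b))
}

new_allometric_fit <- function(group, method, n, intercept_log10,
                               se_intercept_log10, b, se_b, r2, df_resid,
                               lambda_hat = NA_real_, loglik = NA_real_) {
  a <- 10^intercept_log10
  structure(
    list(
      group = group, method = method, n = as.integer(n),
      a = a, se_a = delta_method_se_a(intercept_log10, se_intercept_log10),
      b = b, se_b = se_b,
      intercept_log10 = intercept_log10,
      se_intercept_log10 = se_intercept_log10,
      r2 = r2, df_resid = df_resid,
      lambda_hat = lambda_hat, loglik = loglik
    ),
    class = "allometric_fit"
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  lam <- if (is.na(x$lambda_hat)) "" else sprintf(", lambda = %.3f", x$lambda_hat)
  cat(sprintf(
    "Allometric fit (%s%s): %s\n  a = %.4g +/- %.3g (ml O2/h at 1 g)\n  b = %.4f +/- %.4f\n  R2 = %.4f, n = %d\n",
    x$method, lam,
    if (is.na(x$group)) "ungrouped" else x$group,
    x$a, x$se_a, x$b, x$se_b, x$r2, x$n
  ))
  invisible(x)
}

#' @export
as.data.frame.allometric_fit <- function(x, ...) {
  data.frame(
    group = if (is.null(x$group) || is.na(x$group)) NA_character_ else x$group,
    method = x$method, n = x$n,
    a = x$a, se_a = x$se_a, b = x$b, se_b = x$se_b,
    intercept_log10 = x$intercept_log10,
    se_intercept_log10 = x$se_intercept_log10,
    r2 = x$r2, lambda_hat = x$lambda_hat,
    stringsAsFactors = FALSE
  )
}

check_xy <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("insufficient data: need at least ", min_n, " points, got ",
         length(x), call. = FALSE)
  }
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    stop("singular design: x is constant", call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordinary least-squares allometric fit on log10 data
#'
#' Fits y = intercept + b * x by OLS with classical n - 2 degree-of-freedom
#' standard errors. The antilogged allometric coefficient `a = 10^intercept`
#' and its standard error (delta method, see [delta_method_se_a()]) are
#' filled in on the returned object.
#'
#' @param x log10 body mass.
#' @param y log10 BMR.
#' @param group optional clade label carried through to the fit object.
#' @return An object of class `allometric_fit` with fields `a`, `se_a`, `b`,
#'   `se_b`, `intercept_log10`, `se_intercept_log10`, `r2`, `n`, `method`.
#' @examples
#' fit_ols(x = c(0, 1, 2, 3), y = c(0.5, 1.2, 1.9, 2.7))
#' @export
fit_ols <- function(x, y, group = NA_character_) {
  check_xy(x, y)
  fit <- lm(y ~ x)
  s <- summary(fit)
  new_allometric_fit(
    group = group, method = "OLS", n = length(x),
    intercept_log10 = unname(coef(fit)[1]),
    se_intercept_log10 = s$coefficients[1, 2],
    b = unname(coef(fit)[2]), se_b = s$coefficients[2, 2],
    r2 = if (stats::var(y) == 0) 0 else s$r.squared,
    df_resid = fit$df.residual,
    loglik = as.numeric(logLik(fit))
  )
}

#' Weighted least-squares allometric fit
#'
#' As [fit_ols()] but minimizing the weighted residual sum of squares.
#' Weights are normalized internally to mean 1, so the fit (coefficients and
#' standard errors) is invariant to rescaling all weights by a constant.
#' When fitting group-level summaries the natural weights are per-group
#' species counts.
#'
#' @inheritParams fit_ols
#' @param weights positive weights, one per observation.
#' @return An `allometric_fit` with `method = "WLS"`.
#' @export
fit_wls <- function(x, y, weights, group = NA_character_) {
  check_xy(x, y)
  if (length(weights) != length(x)) {
    stop("weights must match the data length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  w <- weights / mean(weights)
  fit <- lm(y ~ x, weights = w)
  s <- summary(fit)
  new_allometric_fit(
    group = group, method = "WLS", n = length(x),
    intercept_log10 = unname(coef(fit)[1]),
    se_intercept_log10 = s$coefficients[1, 2],
    b = unname(coef(fit)[2]), se_b = s$coefficients[2, 2],
    r2 = if (stats::var(y) == 0) 0 else s$r.squared,
    df_resid = fit$df.residual,
    loglik = as.numeric(logLik(fit))
  )
}

#' Delta-method standard error of the antilogged intercept
#'
#' The allometric coefficient is a = 10^c where c is the log10-space
#' intercept. By the delta method, se(a) = a * ln(10) * se(c).
#'
#' @param intercept_log10 log10-space intercept.
#' @param se_intercept_log10 its standard error (>= 0).
#' @return Standard error of `a = 10^intercept_log10`.
#' @export
delta_method_se_a <- function(intercept_log10, se_intercept_log10) {
  if (any(se_intercept_log10 < 0, na.rm = TRUE)) {
    stop("standard error must be non-negative", call. = FALSE)
  }
  10^intercept_log10 * log(10) * se_intercept_log10
}

#' Welch's t-test of a fitted slope against a reference
#'
#' One-sample form: tests a fitted slope b +/- se against an exact constant
#' `b0` (default 3/4, the theoretical metabolic scaling exponent), with
#' t = (b - b0)/se on the fit's residual degrees of freedom. Two-sample form
#' (when `fit2` is supplied): compares two fitted slopes with the
#' Welch-Satterthwaite approximate degrees of freedom. p-values are
#' two-sided.
#'
#' @param fit an `allometric_fit`, or a numeric slope (then `se_b` and `df`
#'   are required).
#' @param b0 reference slope for the one-sample test (ignored when `fit2`
#'   given). Default 0.75.
#' @param fit2 optional second `allometric_fit` (or numeric slope with
#'   `se_b2`, `df2`) for a two-slope comparison.
#' @param se_b,df,se_b2,df2 scalar standard errors / degrees of freedom when
#'   slopes are passed as plain numbers.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' f <- fit_ols(x = rnorm(30), y = rnorm(30, sd = 0.1) + 0.8 * rnorm(30))
#' welch_test_slope(0.85, se_b = 0.05, df = 100)
#' @export
welch_test_slope <- function(fit, b0 = 0.75, fit2 = NULL,
                             se_b = NULL, df = NULL,
                             se_b2 = NULL, df2 = NULL) {
  if (inherits(fit, "allometric_fit")) {
    b1 <- fit$b; s1 <- fit$se_b; d1 <- fit$df_resid
  } else {
    b1 <- fit; s1 <- se_b; d1 <- df
    if (is.null(s1) || is.null(d1)) {
      stop("se_b and df are required when the slope is passed as a number",
           call. = FALSE)
    }
  }
  if (!is.finite(s1) || s1 <= 0) {
    stop("degenerate variance: slope standard error must be > 0",
         call. = FALSE)
  }
  if (is.null(fit2)) {
    t <- (b1 - b0) / s1
    return(list(t = t, df = d1, p = 2 * pt(-abs(t), d1)))
  }
  if (inherits(fit2, "allometric_fit")) {
    b2 <- fit2$b; s2 <- fit2$se_b; d2 <- fit2$df_resid
  } else {
    b2 <- fit2; s2 <- se_b2; d2 <- df2
  }
  if (!is.finite(s2) || s2 <= 0) {
    stop("degenerate variance: slope standard error must be > 0",
         call. = FALSE)
  }
  v <- s1^2 + s2^2
  t <- (b1 - b2) / sqrt(v)
  df_ws <- v^2 / (s1^4 / d1 + s2^4 / d2)
  list(t = t, df = df_ws, p = 2 * pt(-abs(t), df_ws))
}
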