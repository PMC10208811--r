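new_correlate_fit <- function(predictor, response, fit, weighting) {
  t <- fit$b / fit$se_b
  structure(
    list(
      predictor_name = predictor, response_name = response,
      slope = fit$b, intercept = fit$intercept_log10,
      se_slope = fit$se_b, r2 = fit$r2,
      p = 2 * pt(-abs(t), fit$df_resid),
      n = fit$n, weighting = weighting
    ),
    class = "correlate_fit"
  )
}

#' @export
print.correlate_fit <- function(x, ...) {
  cat(sprintf(
    "%s = %.4f %+.4f * %s  (R2 = %.4f, p = %.4g, n = %d%s)\n",
    x$response_name, x$intercept, x$slope, x$predictor_name,
    x$r2, x$p, x$n,
    if (x$weighting == "none") "" else paste0(", weights = ", x$weighting)
  ))
  invisible(x)
}

# Linear fit on raw (not logged) group-level values; reuses the OLS/WLS
# machinery, which only assumes a linear model.
group_level_fit <- function(x, y, weights = NULL) {
  if (is.null(weights)) fit_ols(x, y) else fit_wls(x, y, weights)
}

#' Regress a group-level quantity on clade divergence time
#'
#' Ordinary (or species-count-weighted) least squares of a per-clade value —
#' an allometric coefficient, a scaling exponent, a BMR ratio — on the
#' clade's divergence time in million years ago. This is the group-level
#' second-stage regression relating metabolic organization to evolutionary
#' age.
#'
#' @param values named numeric vector (names = group labels) or a data
#'   frame with columns `group` and `value`.
#' @param meta clade metadata as from [builtin_group_meta()] (columns
#'   `group`, `mya`, and `n_species` if weighting).
#' @param weighted if `TRUE`, weight groups by `n_species`.
#' @return A `correlate_fit`: `slope`, `intercept`, `r2`, `p` (two-sided,
#'   for the slope), `n`, `weighting`.
#' @examples
#' meta <- builtin_group_meta()
#' regress_on_divergence(setNames(meta$a_common, meta$group), meta)
#' @export
regress_on_divergence <- function(values, meta, weighted = FALSE) {
  if (is.data.frame(values)) {
    values <- setNames(values$value, values$group)
  }
  idx <- match(names(values), meta$group)
  keep <- !is.na(idx) & is.finite(values) & is.finite(meta$mya[idx])
  if (sum(keep) < 3L) {
    stop("insufficient data: need at least 3 groups with a value and a ",
         "divergence time", call. = FALSE)
  }
  x <- meta$mya[idx[keep]]
  y <- unname(values[keep])
  w <- if (weighted) meta$n_species[idx[keep]] else NULL
  new_correlate_fit("divergence_time_mya", "value",
                    group_level_fit(x, y, w),
                    if (weighted) "n_species" else "none")
}

#' Activity duration from sleep duration
#'
#' Activity is the complement of sleep over the 24-hour day:
#' activity = 24 - sleep. Inputs outside \[0, 24\] are a domain error;
#' `NA` propagates.
#'
#' @param sleep_duration hours of sleep per day.
#' @return Hours of activity per day.
#' @export
activity_from_sleep <- function(sleep_duration) {
  bad <- is.finite(sleep_duration) &
    (sleep_duration < 0 | sleep_duration > 24)
  if (any(bad)) {
    stop("sleep duration must be within [0, 24] hours", call. = FALSE)
  }
  24 - sleep_duration
}

merge_ratio_meta <- function(ratio_table, meta, column) {
  idx <- match(ratio_table$group, meta$group)
  val <- meta[[column]][idx]
  keep <- !is.na(idx) & is.finite(val) & is.finite(ratio_table$ratio)
  dropped <- ratio_table$group[!keep]
  if (length(dropped)) {
    message("groups without ", column, " (dropped): ",
            paste(dropped, collapse = ", "))
  }
  if (sum(keep) < 3L) {
    stop("insufficient data: need at least 3 groups with both a BMR ratio ",
         "and ", column, call. = FALSE)
  }
  list(ratio = ratio_table$ratio[keep], value = val[keep])
}

#' Activity duration as a function of the BMR ratio
#'
#' OLS regression of clade-mean activity duration (24 h minus sleep) on the
#' dimensionless BMR ratio; a positive slope means clades with higher
#' size-corrected metabolic level are active for more of the day.
#'
#' @param ratio_table a [bmr_ratio_table()].
#' @param meta clade metadata with a `sleep_h` column.
#' @return A `correlate_fit` with response `activity_h`.
#' @export
correlate_activity_bmr <- function(ratio_table, meta) {
  d <- merge_ratio_meta(ratio_table, meta, "sleep_h")
  fit <- new_correlate_fit("bmr_ratio", "activity_h",
                           group_level_fit(d$ratio,
                                           activity_from_sleep(d$value)),
                           "none")
  fit
}

#' Body temperature as a function of the BMR ratio
#'
#' OLS regression of clade-mean body temperature (deg C) on the
#' dimensionless BMR ratio.
#'
#' @inheritParams correlate_activity_bmr
#' @param meta clade metadata with a `tb_c` column.
#' @return A `correlate_fit` with response `tb_c`.
#' @export
correlate_tb_bmr <- function(ratio_table, meta) {
  d <- merge_ratio_meta(ratio_table, meta, "tb_c")
  new_correlate_fit("bmr_ratio", "tb_c",
                    group_level_fit(d$ratio, d$value), "none")
}

#' Paired OLS-minus-PGLS difference regressed on Pagel's lambda
#'
#' Utility for examining how the phylogenetic signal strength relates to the
#' discrepancy between non-phylogenetic and phylogenetic estimates: given
#' per-clade OLS and PGLS fits, regresses (OLS - PGLS) of a chosen
#' parameter on the PGLS lambda estimates.
#'
#' @param ols_fits,pgls_fits lists of `allometric_fit` objects for the same
#'   clades in the same order (PGLS fits must carry `lambda_hat`).
#' @param parameter `"a"` or `"b"`.
#' @return A `correlate_fit` with predictor `lambda_hat`.
#' @export
regress_phylo_effect <- function(ols_fits, pgls_fits,
                                 parameter = c("a", "b")) {
  parameter <- match.arg(parameter)
  stopifnot(length(ols_fits) == length(pgls_fits))
  d <- vapply(seq_along(ols_fits), function(i) {
    ols_fits[[i]][[parameter]] - pgls_fits[[i]][[parameter]]
  }, numeric(1))
  lam <- vapply(pgls_fits, function(f) f$lambda_hat, numeric(1))
  keep <- is.finite(d) & is.finite(lam)
  if (sum(keep) < 3L) {
    stop("insufficient data: need at least 3 clades with both fits",
         call. = FALSE)
  }
  new_correlate_fit("lambda_hat", paste0("delta_", parameter),
                    group_level_fit(lam[keep], d[keep]), "none")
}
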