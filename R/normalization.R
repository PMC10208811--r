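#' Refit a clade intercept at a fixed common scaling exponent
#'
#' Given the common exponent `b_common`, the intercept that minimizes the
#' residual sum of squares of y = b_common * x + c is c = mean(y -
#' b_common * x). Its standard error is sd(y - b_common * x)/sqrt(n); the
#' antilogged coefficient `a_common = 10^c` gets a delta-method error. R2 is
#' 1 - RSS/TSS with RSS taken about the fixed-slope line, so it can be
#' negative if `b_common` is grossly wrong for the clade.
#'
#' @param x,y log10 body mass and log10 BMR for one clade.
#' @param b_common the common scaling exponent (e.g. from [common_slope()]).
#' @param group optional clade label.
#' @return A list: `group`, `a_common`, `se_a_common`, `intercept_log10`,
#'   `se_intercept_log10`, `r2_at_common_b`, `b_common`, `n`.
#' @export
refit_fixed_slope <- function(x, y, b_common, group = NA_character_) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 2L) stop("insufficient data: need at least 2 points", call. = FALSE)
  z <- y - b_common * x
  intercept <- mean(z)
  se <- sd(z) / sqrt(n)
  rss <- sum((z - intercept)^2)
  tss <- sum((y - mean(y))^2)
  list(
    group = group,
    a_common = 10^intercept,
    se_a_common = delta_method_se_a(intercept, se),
    intercept_log10 = intercept,
    se_intercept_log10 = se,
    r2_at_common_b = if (tss > 0) 1 - rss / tss else NA_real_,
    b_common = b_common,
    n = n
  )
}

#' Dimensionless BMR ratio table relative to a reference clade
#'
#' Divides each clade's fixed-slope allometric coefficient by the reference
#' clade's, giving a body-size-free comparison of metabolic level. Because
#' all coefficients are evaluated at the same exponent, the ratio does not
#' depend on the unit of body mass or of BMR; the reference clade's ratio is
#' exactly 1.
#'
#' @param fits either a data frame with columns `group` and `a_common`
#'   (extra columns such as `se_a_common`, `r2_at_common_b` are carried
#'   through), or a list of results from [refit_fixed_slope()].
#' @param reference_group clade used as the denominator (default
#'   `"Passeriformes"`, the highest-BMR clade).
#' @param common_b optional exponent annotation; taken from the fits when
#'   they carry one.
#' @return A data frame of class `bmr_ratio_table` with columns `group`,
#'   `a_common`, `ratio` (plus any carried columns), and attributes
#'   `reference_group` and `common_b`.
#' @examples
#' fits <- data.frame(
#'   group = c("Monotremata", "Marsupialia", "Eutheria", "Palaeognathae",
#'             "Non-Passeriformes", "Passeriformes"),
#'   a_common = c(1.63, 2.69, 3.53, 3.29, 4.65, 6.18))
#' bmr_ratio_table(fits)
#' @export
bmr_ratio_table <- function(fits, reference_group = "Passeriformes",
                            common_b = NULL) {
  if (!is.data.frame(fits)) {
    stopifnot(is.list(fits))
    if (is.null(common_b) && length(fits) &&
        !is.null(fits[[1]]$b_common)) {
      common_b <- fits[[1]]$b_common
    }
    fits <- do.call(rbind, lapply(fits, function(f) {
      data.frame(group = f$group, a_common = f$a_common,
                 se_a_common = f$se_a_common,
                 r2_at_common_b = f$r2_at_common_b,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!all(c("group", "a_common") %in% names(fits))) {
    stop("fits must provide columns 'group' and 'a_common'", call. = FALSE)
  }
  if (!(reference_group %in% fits$group)) {
    stop("reference group '", reference_group, "' not found; available: ",
         paste(fits$group, collapse = ", "), call. = FALSE)
  }
  if (any(fits$a_common <= 0)) {
    stop("allometric coefficients must be positive", call. = FALSE)
  }
  a_ref <- fits$a_common[fits$group == reference_group]
  out <- fits
  out$ratio <- out$a_common / a_ref
  out$ratio[out$group == reference_group] <- 1
  rownames(out) <- NULL
  structure(out,
            class = c("bmr_ratio_table", "data.frame"),
            reference_group = reference_group,
            common_b = common_b)
}

#' @export
print.bmr_ratio_table <- function(x, digits = 3, ...) {
  b <- attr(x, "common_b")
  cat(sprintf("Dimensionless BMR ratios (reference: %s%s)\n",
              attr(x, "reference_group"),
              if (is.null(b)) "" else sprintf(", common b = %.4f", b)))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
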