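#' Phylogenetic covariance matrix from a rooted tree
#'
#' Builds the Brownian-motion expected trait covariance among tips: entry
#' (i, j) is the total branch length shared on the path from the root to the
#' most recent common ancestor of tips i and j, and the diagonal holds
#' root-to-tip distances. Non-ultrametric trees are allowed; the diagonal
#' then simply varies across tips.
#'
#' @param tree a rooted `phylo` object with branch lengths (tip labels
#'   unique, branch lengths >= 0).
#' @return A symmetric numeric matrix with tip labels as dimnames
#'   (the lambda = 1 covariance).
#' @seealso [lambda_transform()], [gls_fit()]
#' @export
vcv_from_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("tree must be a 'phylo' object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; root it first (midpoint or outgroup rooting)",
         call. = FALSE)
  }
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix
#' by `lam`, leaving the diagonal untouched. `lam = 1` is the untransformed
#' Brownian covariance; `lam = 0` removes all phylogenetic signal (diagonal
#' matrix). Values outside \[0, 1\] are rejected; no lambda > 1 extension is
#' offered.
#'
#' @param C covariance matrix from [vcv_from_tree()].
#' @param lam scalar in \[0, 1\].
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam < 0 || lam > 1) {
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  }
  out <- C * lam
  diag(out) <- diag(C)
  out
}

# Cholesky with a one-shot diagonal jitter for semi-definite C
# (e.g. zero-length terminal branches under lambda = 1).
chol_safe <- function(C) {
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    eps <- 1e-8 * mean(diag(C))
    warning("phylogenetic covariance is numerically singular; ",
            "jittering the diagonal by ", format(eps),
            " (zero-length branches?)", call. = FALSE)
    U <- tryCatch(chol(C + diag(eps, nrow(C))), error = function(e) {
      stop("covariance not positive definite even after jitter; ",
           "resolve zero-length or duplicated tips", call. = FALSE)
    })
  }
  U
}

#' Generalized least-squares regression under a phylogenetic covariance
#'
#' Fits y = intercept + slope * x with error covariance proportional to `C`
#' by GLS: beta = (X' C^-1 X)^-1 X' C^-1 y. Computation goes through the
#' Cholesky factor of `C` (the model is fitted by OLS on the whitened data
#' `U^-T y`, `U^-T X` where `C = U'U`); no explicit inverse is formed. The
#' Gaussian log-likelihood uses the profiled ML variance
#' sigma2 = RSS_w / n and includes the log-determinant of `C`. R-squared is
#' computed in the whitened space against the GLS-estimated mean.
#'
#' @param x,y numeric vectors aligned with the rows/columns of `C`.
#' @param C positive-definite covariance (e.g. from [lambda_transform()]).
#' @return A list: `intercept`, `slope`, `se_intercept`, `se_slope`
#'   (with n - 2 df residual variance), `sigma2_ml`, `loglik`, `r2`,
#'   `rss_whitened`, `n`, `df_resid`.
#' @export
gls_fit <- function(x, y, C) {
  n <- length(y)
  if (length(x) != n || nrow(C) != n || ncol(C) != n) {
    stop("x, y and C must have matching dimensions", call. = FALSE)
  }
  if (n < 3L) {
    stop("insufficient data: need at least 3 points", call. = FALSE)
  }
  U <- chol_safe(C)
  X <- cbind(1, x)
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  fit <- lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss_w <- sum(fit$residuals^2)
  sigma2_ml <- rss_w / n
  logdet <- 2 * sum(log(diag(U)))
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1) - logdet / 2
  s2 <- rss_w / (n - 2)
  covb <- s2 * chol2inv(chol(crossprod(Xw)))
  # whitened-space R2 against the GLS mean
  ones_w <- backsolve(U, rep(1, n), transpose = TRUE)
  mu <- sum(ones_w * yw) / sum(ones_w^2)
  tss_w <- sum((yw - mu * ones_w)^2)
  r2 <- if (tss_w > 0) 1 - rss_w / tss_w else NA_real_
  list(
    intercept = unname(beta[1]), slope = unname(beta[2]),
    se_intercept = sqrt(covb[1, 1]), se_slope = sqrt(covb[2, 2]),
    sigma2_ml = sigma2_ml, loglik = loglik, r2 = r2,
    rss_whitened = rss_w, n = n, df_resid = n - 2L
  )
}

#' Maximum-likelihood profile of Pagel's lambda
#'
#' Maximizes the [gls_fit()] log-likelihood over lambda in \[0, 1\] applied
#' through [lambda_transform()]. A coarse grid (default step 0.01) locates
#' the mode; golden-section refinement within one grid cell polishes it to
#' `tol`. The boundary values 0 and 1 are admissible maximizers.
#'
#' @inheritParams gls_fit
#' @param tol refinement tolerance on lambda (default 1e-6).
#' @param grid_step coarse grid spacing (default 0.01).
#' @return A list: `lambda` (the ML estimate), `loglik` (at the estimate),
#'   and `profile`, a data frame of the grid lambdas and log-likelihoods.
#' @export
profile_lambda_ml <- function(x, y, C, tol = 1e-6, grid_step = 0.01) {
  if (length(y) < 4L) {
    stop("insufficient data: lambda profiling needs at least 4 tips",
         call. = FALSE)
  }
  ll_at <- function(lam) gls_fit(x, y, lambda_transform(C, lam))$loglik
  lams <- seq(0, 1, by = grid_step)
  ll <- vapply(lams, ll_at, numeric(1))
  if (any(!is.finite(ll))) {
    bad <- lams[which(!is.finite(ll))[1]]
    stop("non-finite log-likelihood at lambda = ", format(bad), call. = FALSE)
  }
  i <- which.max(ll)
  lo <- max(0, lams[i] - grid_step)
  hi <- min(1, lams[i] + grid_step)
  opt <- optimize(ll_at, interval = c(lo, hi), maximum = TRUE, tol = tol)
  cand_lam <- c(lams[i], opt$maximum)
  cand_ll <- c(ll[i], opt$objective)
  j <- which.max(cand_ll)
  list(lambda = cand_lam[j], loglik = cand_ll[j],
       profile = data.frame(lambda = lams, loglik = ll))
}

normalize_species_labels <- function(labels) {
  gsub("_", " ", trimws(labels))
}

#' Match a species table to a tree, pruning both sides
#'
#' Species names and tip labels are compared after normalization (trimming
#' whitespace and treating underscores as spaces). Species absent from the
#' tree and tips absent from the table are dropped and reported; the
#' retained records are reordered to the pruned tree's tip order.
#'
#' @param records species table (column `species`).
#' @param tree a `phylo` object.
#' @return A list: `records` (aligned to tip order), `tree` (pruned),
#'   `dropped_species`, `dropped_tips`.
#' @export
prune_and_match <- function(records, tree) {
  sp_norm <- normalize_species_labels(records$species)
  tip_norm <- normalize_species_labels(tree$tip.label)
  keep <- intersect(sp_norm, tip_norm)
  if (length(keep) == 0L) {
    stop("no species in common between the table and the tree", call. = FALSE)
  }
  dropped_species <- records$species[!(sp_norm %in% keep)]
  dropped_tips <- tree$tip.label[!(tip_norm %in% keep)]
  pruned <- if (length(dropped_tips)) {
    ape::drop.tip(tree, dropped_tips)
  } else {
    tree
  }
  rec <- records[sp_norm %in% keep, , drop = FALSE]
  ord <- match(normalize_species_labels(pruned$tip.label),
               normalize_species_labels(rec$species))
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, tree = pruned,
       dropped_species = dropped_species, dropped_tips = dropped_tips)
}

#' Phylogenetic allometric fit (PGLS with ML Pagel's lambda)
#'
#' End-to-end phylogenetic regression of log10 BMR on log10 body mass:
#' matches the species table to the tree ([prune_and_match()]), builds the
#' Brownian covariance ([vcv_from_tree()]), profiles Pagel's lambda by
#' maximum likelihood ([profile_lambda_ml()]), and returns the GLS fit at
#' the lambda estimate with delta-method errors on the antilogged
#' coefficient.
#'
#' @param records species table with columns `species`, `mass_g`,
#'   `bmr_mlO2_h` (and optionally `group`).
#' @param tree rooted `phylo` whose tip labels match the species names
#'   (after trimming and underscore/space normalization).
#' @param group optional clade label for the fit object; defaults to the
#'   single group label in `records` when unambiguous.
#' @return An `allometric_fit` with `method = "PGLS"` and `lambda_hat` set.
#' @export
pgls_allometry <- function(records, tree, group = NULL) {
  pm <- prune_and_match(records, tree)
  n <- nrow(pm$records)
  if (n < 4L) {
    stop("insufficient data: PGLS with lambda estimation needs at least 4 ",
         "matched species, got ", n, call. = FALSE)
  }
  if (length(pm$dropped_species)) {
    message("species not in tree (dropped): ",
            paste(pm$dropped_species, collapse = ", "))
  }
  if (is.null(group)) {
    g <- unique(pm$records$group)
    group <- if (length(g) == 1L) g else NA_character_
  }
  tl <- log10_transform(pm$records)
  C <- vcv_from_tree(pm$tree)
  prof <- profile_lambda_ml(tl$x, tl$y, C)
  g <- gls_fit(tl$x, tl$y, lambda_transform(C, prof$lambda))
  new_allometric_fit(
    group = group, method = "PGLS", n = n,
    intercept_log10 = g$intercept, se_intercept_log10 = g$se_intercept,
    b = g$slope, se_b = g$se_slope, r2 = g$r2, df_resid = g$df_resid,
    lambda_hat = prof$lambda, loglik = g$loglik
  )
}
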