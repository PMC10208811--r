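#' Run the full comparative BMR-scaling pipeline
#'
#' Sequences the four analysis stages on one species table: (1) per-clade
#' allometric fits by the chosen method; (2) slope-homogeneity model
#' comparison and the common exponent; (3) clade intercepts refit at the
#' common exponent and the dimensionless BMR ratio table; (4) group-level
#' correlates against divergence time, activity duration, and body
#' temperature where the metadata allows. Optionally writes per-stage
#' CSV/JSON reports plus a small JSON manifest (inputs, seed, package
#' version).
#'
#' @param species species table (see [read_species_table()]) or a path to
#'   one.
#' @param tree optional `phylo` or Newick path; required when
#'   `method = "PGLS"`.
#' @param meta clade metadata (default [builtin_group_meta()]).
#' @param method per-clade fit method: `"OLS"`, `"WLS"` (weights =
#'   per-clade species counts are not meaningful within a clade, so WLS
#'   here weights by within-table `weight` column if present, else equals
#'   OLS), or `"PGLS"`.
#' @param common_b `"auto"` (estimate via [common_slope()]) or a number.
#' @param reference_group reference clade for the ratio table.
#' @param weighted use species-count weighting in the divergence-time
#'   regressions.
#' @param out_dir optional output directory for reports.
#' @param seed optional integer seed (recorded in the manifest; only used
#'   by stochastic methods, of which the standard pipeline has none).
#' @return A list: `fits` (per-clade `allometric_fit`s), `comparison`
#'   (`model_comparison`), `common_b`, `ratio_table`, `correlates` (list of
#'   `correlate_fit`s; present where computable), `manifest`.
#' @export
run_full_pipeline <- function(species, tree = NULL,
                              meta = builtin_group_meta(),
                              method = c("OLS", "WLS", "PGLS"),
                              common_b = "auto",
                              reference_group = "Passeriformes",
                              weighted = FALSE, out_dir = NULL,
                              seed = NULL) {
  method <- match.arg(method)
  if (is.character(species) && length(species) == 1L) {
    species <- read_species_table(species)
  }
  if (is.character(tree) && length(tree) == 1L) {
    tree <- ape::read.tree(tree)
  }
  if (method == "PGLS" && is.null(tree)) {
    stop("method 'PGLS' requires a tree", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  groups <- unique(species$group)
  fits <- lapply(groups, function(gl) {
    sub <- species[species$group == gl, , drop = FALSE]
    if (method == "PGLS") {
      tryCatch(pgls_allometry(sub, tree, group = gl), error = function(e) {
        message("PGLS failed for ", gl, " (", conditionMessage(e),
                "); falling back to OLS")
        tl <- log10_transform(sub)
        fit_ols(tl$x, tl$y, group = gl)
      })
    } else {
      tl <- log10_transform(sub)
      if (method == "WLS" && !is.null(sub$weight)) {
        fit_wls(tl$x, tl$y, sub$weight, group = gl)
      } else {
        fit_ols(tl$x, tl$y, group = gl)
      }
    }
  })
  names(fits) <- groups

  comparison <- fit_pooled_models(species)
  b_common <- if (identical(common_b, "auto")) {
    comparison$common_slope
  } else {
    as.numeric(common_b)
  }

  refits <- lapply(groups, function(gl) {
    sub <- species[species$group == gl, , drop = FALSE]
    tl <- log10_transform(sub)
    refit_fixed_slope(tl$x, tl$y, b_common, group = gl)
  })
  ratio_table <- bmr_ratio_table(refits, reference_group = reference_group,
                                 common_b = b_common)

  correlates <- list()
  try_corr <- function(expr) tryCatch(expr, error = function(e) NULL)
  correlates$ratio_vs_divergence <- try_corr(
    regress_on_divergence(setNames(ratio_table$ratio, ratio_table$group),
                          meta, weighted = weighted))
  correlates$a_vs_divergence <- try_corr(
    regress_on_divergence(setNames(ratio_table$a_common, ratio_table$group),
                          meta, weighted = weighted))
  correlates$activity_vs_ratio <- try_corr(
    correlate_activity_bmr(ratio_table, meta))
  correlates$tb_vs_ratio <- try_corr(correlate_tb_bmr(ratio_table, meta))
  correlates <- Filter(Negate(is.null), correlates)

  manifest <- list(
    package = "bmrscaling",
    version = as.character(packageVersion("bmrscaling")),
    n_species = nrow(species), groups = groups, method = method,
    common_b = b_common, reference_group = reference_group,
    weighted = weighted, seed = seed
  )

  result <- list(fits = fits, comparison = comparison, common_b = b_common,
                 ratio_table = ratio_table, correlates = correlates,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fit_report(fits, file.path(out_dir, "fits.csv"),
                     file.path(out_dir, "fits.json"))
    write_fit_report(as.data.frame(ratio_table),
                     file.path(out_dir, "ratio_table.csv"),
                     file.path(out_dir, "ratio_table.json"))
    jsonlite::write_json(
      list(models = result$comparison$models,
           best_by_bic = result$comparison$best_by_bic,
           common_slope = result$comparison$common_slope,
           common_slope_se = result$comparison$common_slope_se),
      file.path(out_dir, "model_comparison.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE)
    if (length(correlates)) {
      corr_df <- do.call(rbind, lapply(correlates, function(cf) {
        data.frame(predictor = cf$predictor_name,
                   response = cf$response_name, slope = cf$slope,
                   intercept = cf$intercept, r2 = cf$r2, p = cf$p,
                   n = cf$n, weighting = cf$weighting,
                   stringsAsFactors = FALSE)
      }))
      write_fit_report(corr_df, file.path(out_dir, "correlates.csv"),
                       file.path(out_dir, "correlates.json"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
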