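#' Read a species table of body masses and basal metabolic rates
#'
#' Reads a CSV or TSV table with one row per species and the required columns
#' `species`, `group`, `mass_g` (body mass in grams) and `bmr_mlO2_h` (basal
#' metabolic rate in ml O2 per hour). Rows whose mass or BMR is missing,
#' non-numeric, or non-positive are rejected with a per-row report; duplicate
#' species names among the retained rows are an error.
#'
#' @param source path to a delimited text file.
#' @param delimiter `"auto"` (default; sniffs comma vs tab from the header
#'   line), `"comma"`, or `"tab"`. Other delimiters are not auto-detected and
#'   must be pre-converted.
#' @return A `data.frame` with columns `species`, `group`, `mass_g`,
#'   `bmr_mlO2_h`. Rejected rows (if any) are reported via a warning and
#'   attached as attribute `"rejected"`, a data frame with columns `row`
#'   (1-based data row number in the source file) and `reason`.
#' @seealso [write_fit_report()], [builtin_group_meta()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("species,group,mass_g,bmr_mlO2_h",
#'              "A,Passeriformes,20,55", "B,Passeriformes,10,35"), tf)
#' read_species_table(tf)
#' @export
read_species_table <- function(source, delimiter = c("auto", "comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(source)) {
    stop("species table not found: ", source, call. = FALSE)
  }
  header <- readLines(source, n = 1L)
  sep <- switch(delimiter,
    comma = ",",
    tab   = "\t",
    auto  = if (lengths(regmatches(header, gregexpr("\t", header))) >
                lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  )
  raw <- read.csv(source, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, strip.white = TRUE)
  required <- c("species", "group", "mass_g", "bmr_mlO2_h")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[required]
  mass <- suppressWarnings(as.numeric(raw$mass_g))
  bmr <- suppressWarnings(as.numeric(raw$bmr_mlO2_h))

  reason <- rep(NA_character_, nrow(raw))
  reason[!is.finite(mass)] <- "body mass not a finite number"
  reason[is.finite(mass) & mass <= 0] <- "body mass not positive"
  reason[is.na(reason) & !is.finite(bmr)] <- "BMR not a finite number"
  reason[is.na(reason) & bmr <= 0] <- "BMR not positive"
  bad <- which(!is.na(reason))

  out <- data.frame(
    species = as.character(raw$species),
    group = as.character(raw$group),
    mass_g = mass,
    bmr_mlO2_h = bmr,
    stringsAsFactors = FALSE
  )
  if (length(bad)) {
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
    warning(sprintf("rejected %d row(s): %s", length(bad),
                    paste0("row ", bad, " (", reason[bad], ")", collapse = "; ")),
            call. = FALSE)
  }
  dup <- unique(out$species[duplicated(out$species)])
  if (length(dup)) {
    stop("duplicate species name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  attr(out, "rejected") <- data.frame(row = bad, reason = reason[bad],
                                      stringsAsFactors = FALSE)
  out
}

#' Built-in clade metadata: divergence times, sleep, body temperature
#'
#' Returns the fixture table for the nine vertebrate groups used throughout
#' the package: divergence time from the main vertebrate stem (million years
#' ago), the allometric coefficient `a` refit at the group-family common
#' slope (ml O2/h at 1 g; common slope 0.7248 for endotherms, 0.840 for the
#' three ectotherm groups), the free-slope scaling exponent `b`, and the
#' number of extant species. For the six endotherm clades the table also
#' carries group-mean sleep duration (h/day) and body temperature (deg C).
#'
#' The sleep and body-temperature columns are *reconstructed* group means:
#' they are not published as a single table anywhere, and were assembled once
#' from the standard secondary compilations (Campbell & Tobler 1984 and later
#' updates for sleep, with monotreme/ratite additions; Clarke & Rothery 2008
#' and Maloney et al. 2008 for body temperature). They reproduce the
#' well-established contrasts — mammalian sleep about 40% longer than avian,
#' monotremes at 32 deg C, eutherians near 37 deg C, birds near 40 deg C —
#' and should be treated as representative fixtures, not as measurements.
#' Ectotherm groups carry `NA` for both.
#'
#' @param monotremata_divergence `"table"` (default) uses 217 mya, the value
#'   that enters the cross-vertebrate divergence-time regressions; `"stem"`
#'   uses the alternative stem-based estimate of 271 mya. Both values
#'   circulate in the literature.
#' @return A `data.frame` with columns `group`, `mya`, `a_common`, `b`,
#'   `sleep_h`, `tb_c`, `n_species`; one row per group, `group` unique.
#' @examples
#' meta <- builtin_group_meta()
#' meta[meta$group == "Eutheria", "mya"]
#' @export
builtin_group_meta <- function(monotremata_divergence = c("table", "stem")) {
  monotremata_divergence <- match.arg(monotremata_divergence)
  path <- system.file("extdata", "group_meta.csv", package = "bmrscaling",
                      mustWork = TRUE)
  meta <- read.csv(path, stringsAsFactors = FALSE)
  if (monotremata_divergence == "stem") {
    meta$mya[meta$group == "Monotremata"] <- 271
  }
  meta
}

#' The six endotherm clade labels, oldest divergence first
#'
#' @return Character vector of the endotherm group labels used by the
#'   built-in metadata and the default simulation configuration.
#' @export
endotherm_groups <- function() {
  c("Monotremata", "Marsupialia", "Eutheria",
    "Palaeognathae", "Non-Passeriformes", "Passeriformes")
}

# Coerce fit objects to a flat data.frame with a fixed column order.
fit_report_frame <- function(fits) {
  cols <- c("group", "method", "n", "a", "se_a", "b", "se_b",
            "intercept_log10", "se_intercept_log10", "r2", "lambda_hat")
  if (inherits(fits, "allometric_fit")) fits <- list(fits)
  if (is.data.frame(fits)) {
    return(fits)
  }
  stopifnot(is.list(fits))
  rows <- lapply(fits, function(f) {
    if (inherits(f, "allometric_fit")) as.data.frame(f) else as.data.frame(f)
  })
  out <- do.call(rbind, rows)
  keep <- intersect(cols, names(out))
  out[c(keep, setdiff(names(out), keep))]
}

#' Write fits or ratio tables to CSV and JSON reports
#'
#' Serializes a collection of allometric fits (or any flat results table,
#' e.g. a [bmr_ratio_table()]) to a CSV file with a fixed column order and,
#' optionally, a JSON rendering of the same rows. Numbers are written with 15
#' significant digits so that a written file re-read with
#' [read.csv()][utils::read.csv] reproduces the values to at least 12
#' significant digits, and a write-read-write cycle is byte-identical.
#'
#' @param fits an `allometric_fit`, a list of them, or a data frame
#'   (e.g. a ratio table). An empty list writes a header-only CSV.
#' @param csv_path output CSV path.
#' @param json_path optional output JSON path; omitted if `NULL`.
#' @return Invisibly, the data frame that was written.
#' @export
write_fit_report <- function(fits, csv_path, json_path = NULL) {
  if (is.list(fits) && !is.data.frame(fits) && length(fits) == 0L) {
    df <- data.frame(group = character(), method = character(), n = integer(),
                     a = numeric(), se_a = numeric(), b = numeric(),
                     se_b = numeric(), intercept_log10 = numeric(),
                     se_intercept_log10 = numeric(), r2 = numeric(),
                     lambda_hat = numeric(), stringsAsFactors = FALSE)
  } else {
    df <- fit_report_frame(fits)
  }
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) {
    ifelse(is.na(v), NA_character_,
           vapply(v, function(x) format(x, digits = 15, trim = TRUE,
                                        scientific = FALSE), character(1)))
  })
  ok <- tryCatch({
    write.csv(fmt, csv_path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write report to ", csv_path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(df)
}
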