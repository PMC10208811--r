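Package: bmrscaling
Title: Allometric Scaling of Basal Metabolic Rate Across Endotherm Clades
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of basal metabolic rate (BMR) scaling with
    body mass across the principal clades of mammals and birds. Fits log-log
    allometric regressions by ordinary, weighted, and phylogenetic generalized
    least squares (PGLS) with maximum-likelihood estimation of Pagel's lambda;
    tests slope homogeneity across clades by information-criterion comparison
    of nested pooled models; renormalizes clade intercepts to a common scaling
    exponent to form a dimensionless BMR ratio relative to a reference clade;
    and regresses scaling parameters and the BMR ratio on clade divergence
    time, sleep/activity duration, and body temperature. Includes a
    phylogenetically structured synthetic-data generator so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
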