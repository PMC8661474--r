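Package: lipidnrr
Title: Immune-Lipid Association Networks from Matched Cohorts via
    Non-Rejection-Rate Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of matched patient-control omics cohorts
    combining plasma lipidomics with inflammatory-marker panels.  Implements
    detection-limit cleaning with half-minimum imputation, log2 transformation
    and autoscaling, matched-pair fold-change construction, pairwise Spearman
    correlation, Monte-Carlo estimation of non-rejection rates (NRRs) from
    q-order partial-correlation tests to filter likely-spurious associations,
    mediator-centric network extraction with GraphML export, strong-candidate
    identification, per-feature group testing (ANOVA/Tukey HSD) and a
    medication-confounder scan with multiple-testing correction.  Includes a
    synthetic-cohort generator with a planted sparse precision matrix so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
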