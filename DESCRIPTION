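Package: pglr
Title: Brain-Region Enrichment of Gene Sets with Cohort Matching and
    Volumetric Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates brain regions where a gene set — typically the
    predicted mRNA targets of a microRNA — is co-expressed above the
    background of all other genes, using a multi-donor region-by-gene
    expression atlas in the shape of the Allen Human Brain Atlas.
    Per-region Wilcoxon rank-sum tests with Bonferroni control are
    aggregated across donors into ranked regions of interest, with
    split-half and random-gene-list robustness checks.  Companion tools
    match psychiatric case and control cohorts by Euclidean distance on
    demographics and diagnosis flags, and run the downstream volumetric
    and clinical statistics (intracranial-volume normalisation, rank-sum
    and t comparisons, regressions, correlation matrices, sensitivity
    re-runs).  A synthetic-data generator emulates both the atlas and the
    inpatient cohort so every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
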