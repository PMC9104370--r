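Package: metaboclust
Title: Metabolic Subtype Discovery and Pan-Cancer Association Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers metabolic subtypes of tumor cohorts by clustering
    samples on the expression of metabolic gene sets (a Duda-Hart gate for
    cluster separation, partitioning around medoids on a Spearman
    correlation distance, and silhouette-based selection of the number of
    clusters), derives per-sample molecular and clinical features (SGOL
    copy-number region scores, global methylation, gene-level mutation
    calls, tie-randomized miRNA ranks, survival endpoints), and
    systematically tests subtype-feature associations with
    variable-class-specific tests, validity rules, and per-class Bonferroni
    correction across tumor types. Includes a seeded multi-omic cohort
    simulator with planted subtype structure and planted effects so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
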