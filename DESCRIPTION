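Package: smrlink
Title: Summary-Data Mendelian Randomization Linking GWAS and eQTL Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates GWAS and eQTL summary statistics to nominate genes
    whose expression changes may drive a complex trait. Reads delimited
    summary-statistic tables with configurable column layouts, intersects
    SNPs across studies and aligns effect alleles, computes per SNP-probe
    pair the squared-Z ratio statistic referred to a one-degree-of-freedom
    chi-square distribution, applies probe-count Bonferroni thresholds,
    calls risk genes, and reports cross-dataset gene overlaps. Ships a
    two-cohort synthetic summary-statistics generator so calibration,
    power, and effect recovery of the full pipeline can be tested without
    access to the original data deposits, plus a command-line entry point
    orchestrating the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pheatmap,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
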