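Package: nof1omics
Title: Longitudinal Multi-Omic and Spatial Analysis of Single-Subject Tumor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational procedures used in N-of-1
    longitudinal tumor studies: error-corrected circulating tumor DNA (ctDNA)
    panel analysis with a Bayesian beta-overlap detection statistic, cross-biopsy
    somatic variant classification and exhaustive ordinary-least-squares
    minimum-evolution phylogenies, regulon-based transcriptional-regulator
    activity scoring, reverse-phase protein array (RPPA) pathway and PAM50
    subtype scores, tumor mutational burden and neoepitope filtering, and
    spatial single-cell composition and distance-to-matrix statistics. Includes
    seeded synthetic-data generators emulating the statistical structure of each
    assay so that every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
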