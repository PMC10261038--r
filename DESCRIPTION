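Package: vigormet
Title: Biomass Heterosis Phenotyping and Metabolite Profiling for Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and classifies biomass heterosis (hybrid vigor) in
    reciprocal F1 hybrids relative to mid-parent and better-parent values,
    and identifies heterosis-associated metabolite signatures from
    GC-TOF-MS peak-area matrices. Provides germination-time (t50)
    estimation and sowing synchronization, seed-area screening against a
    control accession, internal-standard normalization and log2
    preprocessing of metabolite matrices, per-peak differential tests with
    Benjamini-Hochberg FDR control and fold changes against the mid-parent
    value, fumarate/malate ratio analysis with ANOVA and Tukey compact
    letter displays, and principal component analysis of metabolite
    profiles. A synthetic-data generator with known ground truth makes
    every stage testable without external measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
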