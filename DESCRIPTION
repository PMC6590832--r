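Package: bottlepi
Title: Bottleneck History, Pooled Nucleotide Diversity and Evolutionary
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking population-bottleneck history, nucleotide
    diversity estimated from pooled sequencing, and evolutionary responses
    in replicated experimental-evolution lines. Provides closed-form
    inbreeding theory (the two-generation inbreeding recursion, harmonic-mean
    effective population size, drift decay of heterozygosity), a Wright-Fisher
    synthetic-cohort generator that emulates bottlenecked Drosophila lines
    with pooled genotyping-by-sequencing read tables and ten-generation trait
    trajectories, nucleotide-diversity estimation from variant tables with the
    coverage and frequency filters used for pooled calls, per-line response
    slopes and viability changes, and a predictor comparison of diversity
    against expected inbreeding via encompassing (combined-model) regression
    with partial-F tests, Welch t contrasts and Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
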