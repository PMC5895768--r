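Package: addercycle
Title: Bacterial Cell-Cycle Analysis with the Adder Model and Multifork
    Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the Escherichia coli cell cycle in
    steady-state exponential populations. Implements the
    Cooper-Helmstetter population relations (mean genome equivalents per
    cell, inversion for the D period, terminal-period estimation from
    cell-class fractions, the steady-state age distribution), a
    single-cell multifork chromosome-replication state machine with
    rifampicin run-off simulation, construction of sibling lineages
    born from one asymmetric division under the adder size-homeostasis
    rule with initiation scheduled a fixed C+D before each division, and
    an image-cytometry pipeline for DAPI-stained cells (fluorescence
    calibration against a reference population, constriction
    classification, small/large contrasts with Welch tests, nucleoid
    segregation metrics, normalized collective profiles, division
    asymmetry). A synthetic-population generator with known ground truth
    makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
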