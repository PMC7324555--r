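Package: plasfit
Title: Plasmid Fitness Cost and Compensatory Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of plasmid fitness-cost and
    compensatory-evolution experiments in bacteria. Estimates relative
    fitness (W) from serial-transfer competition assays, plasmid
    persistence and conjugation frequency, and PCR band-intensity
    competition readouts; computes plasmid copy number from per-replicon
    sequencing coverage; summarises colony-diameter distributions; calls
    differentially transcribed ORFs with a replicate-consistent RPKM
    fold-change rule; and tests COG functional-category enrichment with
    the one-sided hypergeometric (Fisher exact) tail. A synthetic-data
    module simulates serial-transfer competition dynamics (shared-capacity
    logistic growth with conjugation, segregational loss and compensatory
    mutation), whole-genome read allocation at a chosen plasmid copy
    number, lognormal expression matrices with planted fold-changes,
    colony-diameter samples and decaying band-intensity series, so every
    analysis stage can be exercised and validated without raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
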