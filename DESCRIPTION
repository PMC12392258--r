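Package: ntaprob
Title: Identification Probability for Nontargeted LC-HRMS Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrant-free annotation support for reversed-phase LC-HRMS
    nontargeted analysis. Implements retention-time-index (RTI) prediction
    from molecular fingerprints and from cumulative neutral losses (CNL)
    with leverage-based applicability domains, a seven-parameter spectral
    library matcher, a true-positive-probability classifier for individual
    spectral matches with FDR-calibrated probability cut-offs, and an
    identification-probability calculus that converts multi-hit annotation
    ambiguity into a single per-compound probability. Includes a synthetic
    data generator so the whole pipeline is testable without instrument
    data, plus readers and writers for MSP/MGF spectra and compound tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
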