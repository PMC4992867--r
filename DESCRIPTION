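Package: nucleoflux
Title: Promoter Activity and Chromosomal Position Effects from Microplate
    Reporter Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bacterial promoter activity from microplate
    fluorescent-reporter time courses. Implements blank correction of
    optical density, background correction of fluorescence against a
    non-fluorescent reference strain, per-biomass expression (F/OD),
    discrete promoter activity as the first difference of F/OD, and a
    spline-based reporter synthesis-rate estimator using least-squares
    cubic B-splines with Schoenberg-Whitney knot selection. Quantifies
    oxidative-stress induction responses per chromosomal insertion
    position and normalizes them within genetic backgrounds. Ships a
    synthetic plate generator emulating growth phases, growth-phase
    promoter programs, replication-associated gene dosage, and
    genotype-specific position effects, so every pipeline stage can be
    validated against known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
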