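Package: qeegcsa
Title: Compressed Spectral Array Analysis of Quantitative EEG for
    Prodromal Dementia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative EEG analysis of resting-state recordings via
    per-epoch spectral decomposition and compressed spectral arrays (CSA).
    Computes the six CSA descriptors (dominant frequency, DF range, DF
    variability, frequency prevalence, band inscription, frequency ratio)
    from posterior derivations, classifies recordings into six rule-based
    EEG patterns ranging from stable alpha to unstable low frequency, and
    predicts conversion of mild cognitive impairment to dementia with Lewy
    bodies versus Alzheimer's disease from the pattern at the MCI stage.
    Includes a seeded synthetic-EEG cohort generator whose per-epoch
    dominant-frequency trajectories follow each pattern archetype, plus
    cohort-level confusion summaries and correspondence analysis.
License: MIT
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
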