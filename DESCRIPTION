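Package: graphokin
Title: Handwriting Kinematics for Neurodegenerative Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing online handwriting recorded on a graphics
    tablet as a digital biomarker for neurodegenerative disease screening.
    Reads raw pen trajectories (coordinates, pressure, pen state,
    timestamps), segments them into on-paper strokes and in-air movements,
    and extracts a 48-dimensional per-task descriptor set spanning
    kinematics, stroke geometry, Shannon and Renyi entropies,
    Teager-Kaiser energy, signal-to-noise ratios, and the entropy of the
    first intrinsic mode function from empirical mode decomposition.
    Assembles subject-by-(task x feature) cohort matrices with
    leakage-free imputation and normalization, runs nested cross-validated
    feature-selection and classification sweeps with dynamic soft and hard
    voting ensembles, analyses task- and feature-selection frequencies and
    empty-recording censuses, and simulates labelled synthetic cohorts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    randomForest,
    glmnet,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
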