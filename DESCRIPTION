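Package: crcrisk
Title: Reference-Range Risk Scoring and Model Benchmarks for Non-Invasive
    Colorectal Cancer Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a continuous colorectal-cancer risk score from routine
    clinical variables by measuring each analyte's percentage deviation from
    its healthy reference range, combining deviations through per-variable
    "weights of risk" (near-uniform, deflection-proportional, or a combined
    banded scheme), and normalizing against a worst-case fictive patient so
    the score lives on a 0-100 probability-like scale. Ships a seeded
    synthetic-cohort generator emulating an augmented 200-to-900-record
    clinical dataset, Boolean out-of-range labeling, a classification bench
    over six model families under k-fold and holdout validation regimes with
    confusion-matrix metrics and an integer confusion back-solver, and a
    regression bench of feedforward networks trained with a hand-written
    Levenberg-Marquardt optimizer across a ten-architecture sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    tools,
    MASS,
    rpart,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
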