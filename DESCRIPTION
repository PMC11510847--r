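Package: sevensload
Title: GNSS Zone Kinematics and Mixed-Model Workload Prediction for Rugby Sevens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying athlete workload in women's rugby sevens from
    10 Hz GNSS speed traces. Categorises distance into twelve speed-by-
    acceleration zones with individualised sprint-entry thresholds, fuses zone
    distances with contact counts and athlete mass into player-match records,
    fits a random-intercept linear mixed model predicting session rating of
    perceived exertion (sRPE), and evaluates actual versus model-predicted
    workload across tournament game numbers with a repeated-measures ANOVA and
    Tukey post hoc tests. Ships a seeded, calibrated synthetic match generator
    (semi-Markov movement model) that emulates the statistical profile of
    international tournament data, for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
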