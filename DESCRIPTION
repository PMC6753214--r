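Package: conselect
Title: Consensus Predictor Selection and Validation for Clinical
    Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops and internally validates clinical prediction models
    from randomized-trial cohorts using a staged algorithm: bivariable
    screening of candidate covariates with the baseline outcome forced in,
    factor-analytic reduction of collinear candidates, consensus variable
    selection across forward, backward and Lasso processes, model
    characterization (adjusted R-squared, c-statistic), robustness checks,
    whole-pipeline bootstrap optimism correction, and nomogram
    construction. Includes a synthetic titration/randomization trial
    cohort simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
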