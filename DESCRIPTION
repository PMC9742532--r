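Package: dmscreen
Title: Cost-Effectiveness Evaluation of Risk-Based Diabetes Screening Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates population-based cohorts with realistic fasting and
    post-load glucose structure, applies questionnaire risk scores and
    trainable machine-learning classifiers as diabetes screening strategies,
    runs four screening-to-confirmation cascades (risk model alone, or
    preceded by an FPG, 2h post-load glucose, or HbA1c laboratory screen),
    and evaluates each strategy's health-economic profile: the proportion of
    participants requiring a confirmatory test, the average detection cost
    per participant, and the potential complication cost attributable to
    missed (false-negative) cases over 5-25 year horizons. Includes ROC and
    precision-recall machinery with stratified bootstrap confidence
    intervals, the DeLong test for paired AUCs, and matched-sensitivity /
    matched-cost strategy comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml,
    withr,
    class,
    e1071,
    nnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
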