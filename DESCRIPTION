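Package: pvqnet
Title: Discrete Bayesian Networks for Psychological Vulnerability Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for recognizing states of psychological
    vulnerability to suicidal behavior from a 25-item questionnaire
    (OQ-45.2, DEQ and RFL subsets) plus sociodemographics. Provides
    questionnaire ingest and validation, psychometric feature construction
    (reverse-keyed composites, principal-component quadrants, quantile
    discretization), a discrete Bayesian-network engine with expert arc
    constraints (whitelist/blacklist), score-based structure search
    (hill-climbing and tabu search over BIC or BDeu), Dirichlet
    posterior-mean parameter estimation, exact inference by variable
    elimination, per-patient risk profiling with protective/risk factor
    attribution, cross-validated evaluation (leave-one-out and repeated
    stratified k-fold), group-comparison descriptive statistics, and a
    synthetic cohort generator with a known ground-truth network for
    end-to-end recovery testing.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
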