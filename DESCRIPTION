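Package: ccmq
Title: Scoring, Classification and Prevalence Analysis for the Nine TCM
    Body Constitutions (CCMQ)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Constitution in Chinese Medicine Questionnaire
    (CCMQ, 2016 revision; 54 items administered as 57 five-point Likert
    questions) analysis pipeline used in cross-sectional constitution
    epidemiology: converted-score computation on the 0-100 scale, the
    ZZYXH/T157-2009 decision rules assigning each respondent a balanced
    constitution, unbalanced constitutions, unbalanced tendencies or no
    classification, a quality-control exclusion cascade (missing responses,
    low-engagement middle-response patterns, unclassifiable profiles),
    composite-constitution coexistence analysis with chord-diagram data
    export, subgroup prevalence estimation with chi-squared and linear-trend
    tests under Bonferroni correction, and modified Poisson regression with
    robust standard errors yielding adjusted prevalence ratios and
    marginally standardized prevalences. A synthetic respondent generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
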