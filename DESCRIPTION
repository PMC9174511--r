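Package: itqnet
Title: Scoring, Factor, Network, and Epidemiological Analysis of the
    International Trauma Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the ICD-11 International Trauma Questionnaire (ITQ)
    and the International Trauma Exposure Measure (ITEM): the PTSD/complex-PTSD
    diagnostic scoring algorithm, subscale reliability, polychoric correlation
    and weighted-least-squares confirmatory factor analysis of the competing
    ITQ factor models, EBIC-regularized partial-correlation symptom networks
    with centrality indices, and trauma-exposure epidemiology (prevalence,
    gender contrasts, multinomial logistic regression of diagnosis on
    intentional and unintentional trauma exposure). Includes a calibrated
    synthetic cohort generator emulating a late-adolescent community sample
    so that every pipeline stage is testable without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mvtnorm,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
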