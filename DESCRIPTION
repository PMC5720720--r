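Package: ckdmsm
Title: Marginal Structural Cox Models for Antiretroviral Regimens and
    Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of antiretroviral regimen type on
    the risk of chronic kidney disease (confirmed eGFR below 60 ml/min/1.73m2)
    in longitudinal HIV cohorts, where declining renal function drives
    clinicians to switch patients away from tenofovir-containing regimens
    (treatment-confounder feedback). Implements MDRD eGFR computation,
    eligibility screening, five-category regimen classification, confirmed-CKD
    event detection, person-month expansion with last-value-carried-forward
    covariates, traditional Cox models under several exposure codings,
    stabilized inverse-probability-of-treatment-and-censoring weights built
    from polytomous and pooled logistic models with restricted cubic spline
    time intercepts, weighted (marginal structural) and doubly robust Cox
    estimators with clustered sandwich variance, and negative-binomial models
    of regimen discontinuation versus current eGFR. A synthetic cohort
    generator with a counterfactual oracle mode supports calibration and
    parameter-recovery studies.
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
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
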