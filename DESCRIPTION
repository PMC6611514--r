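Package: her2lyg
Title: Population-Level Life Years Gained from Adjuvant Trastuzumab in
    HER2-Positive Early Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Epidemiological and health-economic model estimating the
    life years gained (LYG), disease-free life years gained (DFLYG),
    incremental direct costs and cost-effectiveness of adding adjuvant
    trastuzumab to chemotherapy for HER2-positive early breast cancer,
    accumulated over annual incidence cohorts followed to a fixed
    horizon.  Provides Poisson-regression incidence projection and
    target-population filtering, pseudo individual-patient-data
    reconstruction from digitized Kaplan-Meier curves, right-censored
    Weibull maximum-likelihood fitting and extrapolation, background
    mortality adjustment against a life table, partitioned-survival and
    Markov-cohort progression accounting, full direct-cost computation
    (regimen dosing, statutory price deductions, CPI adjustment, one-off
    recurrence costs), scenario assembly with market shares, incremental
    cost-effectiveness ratios and a deterministic sensitivity-analysis
    driver.  A synthetic-data generator emulates all required inputs so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
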