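Package: fpem
Title: Family Planning Estimation Model for Contraceptive Prevalence
    Indicators
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian hierarchical estimation and projection of family
    planning indicators among married or in-union women of reproductive age:
    modern contraceptive prevalence (mCPR), unmet need for modern methods,
    and demand satisfied with modern methods. Country trends follow a
    logistic growth curve with parameters shared across a country,
    subregion, region, world hierarchy; AR(1) distortions on annual rates of
    change capture departures from the expected trend. The observation model
    accounts for survey reference periods, sampling variances (computed or
    imputed), source-specific non-sampling error and bias, and supplementary
    service-statistic (EMU) series. Includes population-weighted aggregation
    with full uncertainty propagation, additional-users accounting, a
    counterfactual "pre-2012 expectation" analysis with attainment
    probabilities, and a synthetic-data generator mirroring the model's
    generative assumptions for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
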