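Package: survjack
Title: Jackknife Value Estimation for Survival Individualized Treatment Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the value function of individualized treatment rules
    (ITRs) for right-censored survival outcomes with a leave-one-out
    cross-validation (jackknife) estimator adjusted by inverse probability of
    censoring weighting (IPCW). Provides treatment-rule learners based on
    restricted mean survival time (random survival forest, Cox proportional
    hazards with treatment interactions, and the one-size-fits-all zero-order
    model), a closed-form variance estimator built on influence residuals, a
    paired Z-test for comparing two rules, accelerated failure time and
    proportional hazards scenario simulators with censoring-rate calibration,
    and batch drivers that regenerate power, size, and normality summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
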