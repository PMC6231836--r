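Package: stepincentives
Title: Simulation and Longitudinal Evaluation of an Adaptive Step-Goal
    Micro-Incentive Walking Program
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executable model of a population-scale mobile walking program that
    pays very small loyalty-point rewards (Can $0.04/day) for meeting
    personalized, adaptively increasing daily step goals, together with the
    full quasi-experimental evaluation pipeline used to assess it. Includes a
    seeded synthetic step-diary generator calibrated to the program's reported
    baseline marginals, the day-by-day program state machine (validity
    filtering, baseline goal assignment, 14-day step-up challenges, reward
    ledger), construction of the three missing-data analytic samples
    (any-data, completer, baseline-carried-forward), and random-intercept
    mixed-effects weekly-means analysis with covariate-adjusted least-square
    means, Wald confidence intervals, local Cohen f-squared effect sizes,
    subgroup stratification, and engagement moderation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
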