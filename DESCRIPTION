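Package: costconseq
Title: Cost-Consequence Analysis of Early Intervention Trials with
    Temporal Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for trial-based cost-consequence analysis of early
    interventions for autistic children, modelled on the Preschool Autism
    Communication Trial (PACT). Generates calibrated synthetic per-child
    resource-use cohorts, costs them with country-specific unit prices at
    2020 euro levels, aggregates costs under healthcare-service, broader
    service and societal perspectives, projects 13-month trial costs over
    a 6-year horizon with schedule rules and 3.5% discounting, quantifies
    uncertainty by non-parametric bootstrap, decomposes incremental costs
    as waterfall series, and runs deterministic sensitivity analyses
    (unit-cost scaling, parental-hours taper, out-of-pocket comparison).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
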