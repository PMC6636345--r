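Package: cohortwatch
Title: Active Drug Surveillance with New-User Cohorts, Propensity Matching
    and Survival Analysis on EMR Tables
Version: 0.1.0
Authors@R: person("Cohortwatch", "Maintainers", email = "maintainers@cohortwatch.org",
    role = c("aut", "cre"))
Description: A file-based pipeline for comparative drug safety and
    effectiveness studies on electronic-medical-record style tables.
    Implements new-user cohort identification with washout, attrition
    ("cohort tree") reporting, incident-outcome subcohorts, lookback
    covariate assembly, propensity-score estimation by logistic regression
    with 1:1 greedy nearest-neighbor caliper matching and standardized
    mean difference balance diagnostics, intention-to-treat and as-treated
    follow-up construction with refill-gap drug-era logic, incidence
    density and exact binomial cumulative incidence, Kaplan-Meier curves
    with Greenwood variance, and Cox proportional hazards fitting by
    Newton-Raphson on the partial likelihood with Efron or Breslow tie
    handling. Ships a synthetic EMR generator with known ground truth so
    the whole system is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
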