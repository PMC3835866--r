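Package: sgapaf
Title: Population Attributable Fractions for Small-for-Gestational-Age Birth
    from Linked Perinatal Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for population-level risk-factor studies of
    small-for-gestational-age (SGA) birth using longitudinally linked
    perinatal registry records. Classifies births against a gestational-age-
    and sex-specific birthweight percentile standard, derives obstetric-history
    covariates from each mother's linked birth sequence, screens and selects
    risk factors by backward elimination with a change-in-estimate confounder
    rule, fits marginal logistic models by generalised estimating equations
    with an exchangeable working correlation over births to the same mother and
    robust (sandwich) standard errors, and estimates model-based population
    attributable fractions by coefficient-zeroing counterfactuals with
    bias-corrected cluster-bootstrap confidence intervals. Includes a synthetic
    linked-cohort generator with a ground-truth ledger so every stage is
    testable without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
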