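Package: neobili
Title: Individual Bilirubin Progression Forecasting and Validation in Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts individual total bilirubin progression in neonates from
    one to three early postnatal measurements, using a maturation-driven
    turnover model embedded in a nonlinear mixed-effects framework with
    empirical Bayes (MAP) estimation of individual random effects. Provides a
    synthetic neonatal cohort generator, a rule-based builder of clinical
    validation scenarios for serum (TSB) and transcutaneous (TcB) bilirubin
    measurements, the full prospective-validation metric set (signed, absolute
    and relative prediction errors, Bland-Altman margin of error, clinical
    acceptance and exactness criteria, TcB-TSB harmonization, bilirubin rate
    of increase), and an end-to-end study pipeline with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
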