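Package: capamg
Title: Needs-Based Capitation Financing from Morbidity-Adjusted Cost Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building needs-based capitation financing models for
    regional health services from person-level healthcare cost data stratified
    by sex, age band, and Adjusted Morbidity Group (AMG). Fits generalized
    linear models for strictly positive, right-skewed annual costs over the
    standard family/link menu used in health econometrics, selects the link by
    Box-Cox profile likelihood and the distribution family by the Modified
    Park test, and validates the chosen model with a specification battery
    (Pregibon link test, modified Hosmer-Lemeshow test, Copas cross-validation
    test) plus raw-scale fit metrics. From the fitted model it derives per-AMG
    average marginal effects, predicted mean costs and relative cost weights,
    per-area need indices and adjusted populations, and a three-way allocation
    of a fixed regional budget (by population, by adjusted population, and by
    historical cost). A calibrated synthetic-population generator reproduces
    the statistical structure of the 2017 Murcian Health Service analytic
    population so that every stage is testable without access to the
    confidential person-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
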