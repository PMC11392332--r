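Package: bpjoint
Title: Joint Bivariate Regression Modelling of Systolic and Diastolic
    Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the two-response linear regression model with
    bivariate-normal errors used to analyse systolic and diastolic blood
    pressure jointly, including the residual-correlation estimate,
    cross-equation coefficient-equality F tests, the Breusch-Pagan test of
    residual independence, a bivariate Shapiro-Wilk normality check,
    collinearity and exploratory predictor screening, and survey-aware
    (weighted, cluster-robust) inference. Ships a synthetic cohort
    generator emulating the structure of a national stepwise
    non-communicable-disease risk-factor survey so the complete screening
    and modelling pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
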