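Package: qbill
Title: Quantile Regression and Variable Selection for Health-Care Billing Aggressiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing provider billing
    aggressiveness (the ratio of average submitted charge to average
    payment) from Medicare-style provider-procedure claim summaries.
    Implements exact linear-programming quantile regression under the
    asymmetric Laplace likelihood, L1-penalized quantile regression with
    a modified-BIC penalty-level selection rule, an OLS baseline with
    Lilliefors residual-normality diagnostics, bootstrap confidence
    bands, and a synthetic claims generator with known quantile-varying
    coefficients for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    datasets,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
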