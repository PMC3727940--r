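Package: pemfrail
Title: Piecewise Exponential Hazard Models with Gamma Frailty for Recurrent Injury Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of parametric baseline hazards (exponential,
    Weibull, K-piece exponential) for recurrent time-to-event data on the job clock,
    with gamma frailty for within-worker correlation. Includes counting-process data
    handling and episode splitting, a synthetic occupational-injury cohort generator,
    data-driven changepoint estimation by profile likelihood with employee-level
    bootstrap, cross-validated model selection (likelihood ratio tests, BIC, Bayes
    factors), fully-conditional-specification multiple imputation with Rubin's-rules
    pooling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite
Config/testthat/edition: 3
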