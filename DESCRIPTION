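Package: serialmed
Title: Serial Two-Mediator Analysis of Pain and Functional Dependence
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal serial mediation analysis with two mediators and a
    binary outcome, as used in cohort studies of arthritis: scoring of the
    CESD-10 depression scale (with single-item imputation), a configurable
    PASE-style physical-activity composite, dichotomization of a 1-5
    functional-limitation classification, ordinary least squares and logistic
    path models, product-of-coefficients indirect effects on the log odds
    ratio scale, percentage-mediated summaries, percentile bootstrap
    inference, and a synthetic cohort generator calibrated to published
    marginals so the full pipeline is testable without restricted cohort
    data. Includes sensitivity variants (alternative outcome classification,
    arthritis-subtype subsets, swapped mediator ordering).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
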