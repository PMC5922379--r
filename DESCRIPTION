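Package: episcore
Title: Expression-Based Survival Risk Scores via Maximally Selected Rank Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates dichotomized gene-expression prognostic risk
    scores for right-censored survival endpoints. Screens candidate genes by
    maximally selected rank statistics with a Brownian-bridge p-value
    approximation and Benjamini-Hochberg correction across two cohorts, prunes
    them by multivariate Cox regression, combines the survivors into a
    +/- beta-weighted risk score with count-based risk groups merged by
    sequential log-rank tests, and applies the frozen model to independent
    cohorts. Includes a synthetic-cohort generator with planted step-function
    hazard effects for end-to-end validation, plus the exact contingency,
    t-test, signed-rank and immunohistochemistry cutpoint utilities used in
    clinicopathological association analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    utils,
    stats,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
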