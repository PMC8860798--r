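Package: twinmed
Title: Multilevel Twin Variance-Components Mediation Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how traumatic-event exposure relates to
    post-traumatic stress symptoms directly and indirectly through brain
    region-of-interest volumes in family-and-site clustered cohorts.
    Provides a seeded synthetic-cohort generator with monozygotic/dizygotic
    twin, sibling and singleton clusters nested in study sites; two-parameter
    logistic item factor models for binary symptom items; masking,
    residualization and standardization preprocessing; elastic-net mediator
    pre-selection by coordinate descent with family-stratified
    cross-validation; and a multilevel A/C/E/S variance-components mediation
    structural equation model estimated by full-information maximum
    likelihood over site blocks, with likelihood-ratio and AIC model
    comparison and an eigenvalue-based effective-number-of-tests correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    statmod,
    numDeriv
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mvtnorm,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
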