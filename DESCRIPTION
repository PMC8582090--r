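Package: fallstrat
Title: Stratified Fall-Risk Assessment for Community-Dwelling Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratified fall-risk assessment in community-dwelling
    older adults. Implements a synthetic cohort generator matching published
    percentile marginals, from-scratch binary logistic regression by
    iteratively reweighted least squares (with backward selection and the
    Hosmer-Lemeshow goodness-of-fit test), ROC/AUC discrimination analysis
    with DeLong confidence intervals and cross-validation, and the inversion
    of a multivariate fall-probability model along a joint percentile risk
    profile to derive four-level (low/moderate/high/very-high) interval
    reference cutoffs for eight key risk factors, plus an individual risk
    profiler with improvement deltas.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
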