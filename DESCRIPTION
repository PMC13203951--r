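Package: ekcdm
Title: Ordered-Level Cognitive Diagnosis from Exercise-Knowledge-Cognition
    Requirement Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Cognitive diagnosis for assessments whose items are tagged, per
    exercise-knowledge pair, with an ordered cognitive requirement level
    (0-6, revised Bloom taxonomy) rather than a binary Q-matrix entry.
    Implements a DINA-type response model on the ordered requirement map:
    marginal maximum-likelihood estimation of slip and guess parameters by
    an expectation-maximization algorithm over the enumerated space of
    ordered knowledge-cognition profiles, maximum a posteriori profile
    inference with tie handling, per-concept marginal level posteriors and
    credible intervals, and adjacent-level separability diagnostics.  Also
    provides the accompanying Monte Carlo parameter-recovery harness,
    ordinal inter-rater reliability statistics (Krippendorff's alpha,
    quadratic weighted kappa, bootstrap intervals), and construct-validity
    tests against external cognitive-domain labels (tie-corrected
    Kruskal-Wallis with rank epsilon-squared, Spearman trend).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
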