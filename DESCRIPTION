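Package: mweffect
Title: Rank-Based Tests and Compatible Confidence Intervals for the
    Mann-Whitney Effect
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference for the Mann-Whitney effect (relative effect,
    probabilistic index) theta = P(X1 < X2) + 0.5 * P(X1 = X2) from two
    independent samples of metric or ordered-categorical data, without
    assuming equal distributions or variances (the nonparametric
    Behrens-Fisher problem).  Implements the Brunner-Munzel test with
    Satterthwaite t-approximation, the studentized permutation test, and
    a chi-square test built from the ratio of the unbiased rank-based
    variance estimator to its Birnbaum-Klose upper bound, together with
    the compatible confidence intervals of each test.  The chi-square
    test's Wilson-type interval is range-preserving.  Includes Monte
    Carlo harnesses for type-I error, power and interval coverage, and
    readers for long-format and frequency-table data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
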