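Package: qpcrmlm
Title: Multivariable Linear Models for qPCR Cycle-Threshold Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of qPCR cycle-threshold (CT) data with multivariable
    linear models (ANCOVA), in which the reference-gene CT enters as an
    estimated covariate instead of being subtracted with an assumed weight of
    one. Implements the classic delta-CT and delta-delta-CT (2^-ddCT) methods
    and their t-tests for comparison, efficiency-based CT rescaling, annotated
    CT-table input/output with technical-replicate collapsing, and a seeded
    Monte-Carlo framework that estimates empirical type I error and power of
    the three approaches under varying target-reference correlation,
    distribution skew, and reference-gene contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
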