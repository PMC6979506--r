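Package: lrostats
Title: Moments, Variance Partition and Sensitivity Analysis of Lifetime
    Reproductive Output from Matrix Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements Markov chains with rewards for the analysis of
    lifetime reproductive output (LRO) from any age- or stage-classified
    matrix population model. Provides exact closed-form moments of LRO of
    all orders, derived statistics (variance, standard deviation, CV and
    Crow's opportunity for selection), the decomposition of variance into
    within- and between-pathway components, and complete analytic
    sensitivity and elasticity analysis of all moments and statistics with
    respect to mortality, stage transitions, and the moments of
    stage-specific fertility. Includes an individual-based Monte-Carlo
    simulator for independent validation, readers for COMPADRE-style
    projection-matrix files and life tables, and a synthetic life-cycle
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
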