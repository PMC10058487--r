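Package: blockpath
Title: Global and Partial Block Effects in Multiblock Path Models via PLS
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the effect of an input data block on an outcome in a
    three-vertex path diagram, either on its own (the "global" effect) or
    conditionally on a mediating block (the "partial" effect), as
    cross-validated percentages of explained variance from partial least
    squares (PLS) regression models. Provides from-scratch NIPALS PLS1/PLS2
    with variable importance in projection (VIP), repeated stratified k-fold
    cross-validation with one-standard-error component selection, bootstrap
    VIP summaries, log2 fold-changes, metabolomics-style preprocessing
    (minimum-based zero replacement, log transformation, unit-variance
    scaling), and a synthetic multiblock data generator with closed-form
    population oracles for the unidimensional case.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
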