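Package: drfs
Title: Dual-Regularized Feature Selection for Gene-Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised embedded feature selection that preserves class-specific
    feature-manifold structure while eliminating globally redundant features.
    Class-specific and global k-nearest-neighbour RBF feature-similarity graphs
    define two complementary regularizers on a non-negative feature weight
    matrix fitted by sparse (l2,1-penalized) regression; the optimization uses
    an augmented Lagrangian scheme with multiplicative non-negative updates and
    per-class closed-form solves. Includes a synthetic-data generator with
    planted informative, redundant and noise features, a cross-validated
    evaluation harness (linear SVM and 1-NN), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
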