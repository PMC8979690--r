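Package: histofuse
Title: Deep and Texture Feature Fusion for Histopathology Tile Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-class histopathology tile classification by fusing
    convolutional-network features with classical texture descriptors.
    Implements structure-preserving stain normalization via sparse
    non-negative factorization of Beer-Lambert optical densities, five
    texture descriptors (histogram of oriented gradients, gray-level
    co-occurrence matrix properties, uniform local binary patterns, a Gabor
    filter bank, and Gauss-Markov random field coefficients), an
    AlexNet-shaped feature extractor tapped at the 4096-dimensional fc7
    layer with pluggable weights, class-mean-difference feature selection,
    concatenation fusion, and evaluation with shallow classifiers
    (regularized logistic regression, linear support vector machine, random
    forest). A synthetic two-stain tissue simulator provides labelled
    fixtures so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
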