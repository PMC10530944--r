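Package: swldanet
Title: Stepwise Linear Discriminant Feature Selection over Eigenimage
    Features for Multi-Class Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid pipeline for multi-class classification of 2-D
    grayscale images, aimed at severity grading of brain MRI slices and
    similar medical imaging problems. Images are smoothed with a mean
    (averaging) filter, projected onto the top eigenvectors of the
    training pixel covariance (eigenimage features), reduced by stepwise
    linear discriminant analysis (forward entry and backward elimination
    driven by partial F statistics on an indicator regression), and
    classified with a single-hidden-layer dense neural network trained by
    Adam. Includes a synthetic phantom-image generator, stratified k-fold
    cross-validation with confusion-matrix reports (per-class recognition
    rates, sensitivity, specificity), plug-in baseline classifiers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    png,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    randomForest,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
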