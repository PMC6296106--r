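Package: morphotype
Title: Morphometric Quantification and Supervised Classification of
    Cortical Interneuron Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads SWC neuron reconstructions, computes 103 axonal and
    dendritic morphometrics (55 standard metric/topological measures and 48
    custom quantifications of Petilla features such as arbor orientation,
    laminar distribution, dendritic polarity and type-specific arborization
    patterns), and classifies interneurons into morphological types with
    one-versus-all models trained under repeated stratified cross-validation
    with in-fold Kruskal-Wallis or balanced random-forest feature selection
    and hybrid undersampling plus SMOTE oversampling. Includes a seeded
    synthetic-morphology generator for end-to-end testing without
    reconstruction downloads, quality-control screens for common
    reconstruction defects, and atypical-cell reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    rpart,
    nnet,
    glmnet,
    randomForest,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
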