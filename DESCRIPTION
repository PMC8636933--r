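Package: carcstack
Title: Stacked-Ensemble Carcinogenicity Prediction from Chemical Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary carcinogenicity (QSAR) classification by stacked
    generalization. Five classical learners (k-nearest neighbours, logistic
    regression, support vector machine, random forest, gradient-boosted
    trees) are trained in bulk on subsamples of the training set; a
    performance-based selection rule retains the robust members, whose
    predicted probabilities form a model-level representation that a small
    neural meta-classifier maps to a carcinogenicity probability. Includes
    MACCS fingerprinting and substructure-embedding featurization,
    descriptor preprocessing (zero-variance and correlation filters),
    Kennard-Stone representative splitting, Tanimoto similarity analysis
    for continuous and dichotomous representations, confusion-matrix
    metrics with threshold prioritization, conventional ensemble baselines,
    compound-library screening with probability binning, and a synthetic
    data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
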