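Package: noduleFusion
Title: Hybrid Hand-Crafted and Learned Features for Pulmonary Nodule Patch Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies lung CT image patches as nodule or non-nodule with a
    hybrid feature-extraction pipeline: three hand-crafted descriptors
    (histogram of oriented gradients, an extended HOG with signed-orientation
    folding, and local binary patterns), a small trainable convolutional
    network used as a fourth feature extractor, feature fusion by
    concatenation, and four classifiers (SVM, 1-NN, decision tree, random
    forest) evaluated over a 36-combination grid with a five-split validation
    scheme. Includes a synthetic five-slice patch generator emulating LIDC-style
    nodule/non-nodule stacks, the full evaluation metric panel (accuracy,
    sensitivity, specificity, Cohen's kappa, F-score, PPV/NPV) in the
    confusion-matrix convention used by the published tables, and tools to
    recompute every metric from those printed confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    e1071,
    class,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
LinkingTo: Rcpp
biocViews: Classification, FeatureExtraction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
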