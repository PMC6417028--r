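Package: lesionrad
Title: Radiomic Texture Analysis and Classification of Multi-Sequence MR Lesion Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for two-class discrimination of liver lesions on
    precontrast magnetic resonance images. Computes 1029 radiomic features
    (first-order, shape, GLCM, GLRLM and GLSZM texture, plus the same
    intensity features on exponential, square, square-root, logarithm and
    single-level 3-D wavelet filtered images) from four MR sequences over a
    binary lesion mask, reduces them with a variance threshold, a univariate
    Mann-Whitney filter and LASSO regression, and evaluates decision-tree,
    random-forest, k-nearest-neighbour and logistic-regression classifiers
    by ROC analysis with DeLong AUC comparison. Includes a reproducible
    synthetic lesion-phantom cohort generator with controllable
    class-separating structure, and minimal NIfTI-1 volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    glmnet,
    igraph,
    FNN,
    Matrix
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
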