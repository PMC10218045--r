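Package: asmbplsda
Title: Adaptive Sparse Multi-Block Partial Least Squares Discriminant
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sparse feature selection and classification for multi-omics
    data. Fits adaptive sparse multi-block partial least squares
    discriminant analysis (asmbPLS-DA) models: latent components are
    extracted block-wise with soft-thresholded weight vectors (sparsity
    set per block by a weight quantile), combined through super scores,
    and turned into group assignments by fixed-cutoff, maximum
    Y-estimate, Euclidean, Mahalanobis and PCA-based decision rules,
    optionally combined by unweighted, weighted and ranked votes.
    Includes repeated stratified cross-validation for tuning the
    per-component quantile combinations and the number of components, a
    multivariate-normal multi-block simulation engine with planted
    relevant features for method evaluation, selection and
    classification metrics, delimited-matrix and JSON model input and
    output, and adapters exporting super scores or selected features to
    downstream classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
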