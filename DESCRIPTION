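Package: mfield
Title: Means-Field Riemannian Classifiers for Covariance-Based EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic Riemannian classifiers for brain-computer interface
    decoding of symmetric positive-definite (SPD) trial covariance matrices.
    Implements power means of SPD matrices under the affine-invariant metric
    with robust (outlier-trimming) estimation, the minimum-distance-to-mean
    (MDM) and minimum-distance-to-means-field (MDMF) baselines, and the
    means-field (MF) classifier that feeds squared geodesic distances to a
    field of power means into a linear discriminant. Also provides shrinkage
    covariance estimation from epoched multichannel signals, a two-stage
    adaptive CSP spatial filter built on generalized eigendecomposition and
    Pham's approximate joint diagonalization, stratified cross-validated
    AUC-ROC benchmarking, and meta-analytic comparison statistics (exact
    paired permutation test, Wilcoxon signed-rank, weighted Liptak p-value
    combination, standardized-mean-difference aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
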