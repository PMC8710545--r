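Package: dynconn
Title: Dynamic Functional Connectivity States and Connectome-Based
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis of
    regional BOLD time series: tapered windowed correlation, pooled k-means
    clustering under the Manhattan (L1) distance into recurring brain states,
    per-subject dwell-time and transition statistics, and node-strength
    feature extraction from structural, static functional and dynamic
    functional connectomes.  Includes mass univariate group comparison with
    Benjamini-Hochberg control, ridge-regularized logistic classification
    under repeated nested stratified cross-validation with SMOTE
    oversampling, permutation-based model comparison, feature-weight
    aggregation with a dual-criterion importance rule, and a synthetic-cohort
    generator with latent Markov switching covariance states for end-to-end
    validation without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
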