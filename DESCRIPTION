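Package: bcimatrix
Title: Matrix-Variate Feature Selection and Robust Support Matrix Machines
    for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying multichannel EEG trials kept in their
    native matrix (channels by time) form.  Implements a family of sparse
    and robust principal-component decompositions (sparse PCA, joint-sparse
    PCA with l2,1 penalties, group-sparse PCA, two-dimensional outlier-robust
    PCA, and low-rank plus sparse decomposition by principal component
    pursuit), a multiclass robust support matrix machine regularized by
    l2,1 and nuclear norms and trained by consensus ADMM, and the
    surrounding pipeline: sample sizing with finite-population correction,
    window segmentation and variance-weighted sample allocation, a CSP
    filter bank with mutual-information band selection, time-domain-parameter
    features, chance-corrected evaluation with stratified cross-validation,
    synthetic matrix-variate trial generators, and a plain-text trial
    archive format with a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
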