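Package: paradiomics
Title: Robust Radiomic Feature Selection for Photoacoustic Tumour Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sensitivity and robustness analysis of 3D radiomic features
    extracted from photoacoustic (optoacoustic) tumour images. Provides a
    synthetic phantom cohort emulating two breast-cancer xenograft models
    under varying wavelength, grey-level quantisation and reconstruction
    surrogates; native 3D extraction of 93 first-order and texture-matrix
    features (GLCM, GLDM, GLRLM, GLSZM, NGTDM); balanced full-factorial
    eta-squared variance decomposition with standardisation sweeps and
    k-fold coefficient-of-variation robustness; and a discrimination stage
    with volume-dependency correction, Kruskal-Wallis tests under
    Benjamini-Hochberg false-discovery control, repeated-measures
    correlation pruning and Shapley-value feature ranking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    randomForest,
    xgboost,
    e1071,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
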