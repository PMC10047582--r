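Package: recurmap
Title: Voxelwise Radiomics Mapping of Glioblastoma Recurrence in the
    Peritumoral Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which parts of the glioblastoma peritumoral region
    will turn into recurrent enhancing tumor, from postoperative
    multiparametric MRI.  Implements voxel-based radiomic feature maps
    (first-order and IBSI-style GLCM, GLRLM, GLSZM, NGTDM and GLDM texture
    families over a sliding cubic kernel, with Laplacian-of-Gaussian,
    separable Haar wavelet and local-binary-pattern filtered inputs),
    class balancing by random undersampling, four gradient-ensemble
    classifiers behind a single model interface, probability-map
    postprocessing with a cavity-distance correction factor and Otsu
    thresholding, and both voxelwise and cavity-centered sector (region)
    evaluation with AUC, accuracy, precision, recall, F1 and Cohen's
    kappa.  A synthetic multiparametric phantom generator with known
    recurrence ground truth makes the whole pipeline runnable and
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    ranger,
    xgboost,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
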