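Package: noduleCADx
Title: Texture-Based Computer-Aided Diagnosis of Lung Nodules on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis (CADx) pipeline for classifying lung
    nodules on chest CT as malignant or benign. Volumes are resampled to 1 mm
    isotropic voxels and a 64x64x64 patch is cropped around each annotated
    nodule center; rotation-invariant uniform local binary patterns on three
    orthogonal planes (LBP-TOP) summarize 3D texture; a from-scratch
    regularized gradient tree boosting classifier (binary logistic, second
    order split gain) or an RBF-kernel support vector machine produces
    malignancy probabilities; hyperparameters of the classifier and of the
    texture operator are tuned by random search or a from-scratch Tree Parzen
    Estimator that minimizes the leave-one-out cross-validation log loss, and
    performance is summarized by ROC AUC and accuracy over repeated searches.
    A synthetic 3D texture-phantom generator with controllable class
    separation supports end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
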