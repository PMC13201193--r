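Package: habfuse
Title: Habitat Subregion and Multi-Stream Fusion Modeling of Ground-Glass
    Nodule Invasiveness on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully synthetic-exercisable pipeline for
    preoperative discrimination of indolent (AIS/MIA) versus invasive
    (IAC) lung adenocarcinoma presenting as ground-glass nodules on CT.
    Provides a two-class, two-center nodule phantom generator with
    rater-perturbed masks and clinical covariates; lung-window
    normalization and isotropic resampling; intratumoral habitat
    generation by K-means clustering of 19 voxel-local features with
    Calinski-Harabasz model selection; IBSI-style radiomics feature
    extraction with ICC stability filtering; ComBat-style batch
    harmonization and a Pearson/mRMR/LASSO selection chain;
    residual-network embedding streams (2D/2.5D/3D); early
    (feature-level) and late (out-of-fold stacking) fusion with SVM
    classifiers; and a full evaluation suite (DeLong AUC machinery,
    Hosmer-Lemeshow calibration, decision-curve analysis, cohort
    statistics, and Shapley-value interpretation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    RNifti,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    sva,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
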