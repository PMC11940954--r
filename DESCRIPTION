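Package: infantmotion
Title: Markerless Infant Gross-Motor Assessment from Skeletal Keypoint Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening infant gross-motor development from
    per-frame 17-keypoint pose sequences extracted from home videos.
    Implements confidence filtering, gap interpolation, rolling-mean
    smoothing and trunk-length normalization of skeletal time series;
    segmentation into fixed-length clips with an activity gate; a fixed
    catalog of 227 kinematic, motion and posture features per clip;
    one-way ANOVA feature screening with minority oversampling and
    stratified cross-validated classification (random forest, SVM,
    logistic regression, XGBoost) reporting support-weighted metrics;
    object keypoint similarity (OKS) with threshold-swept mAP/mAR for
    evaluating pose predictions; and a seeded synthetic supine-infant
    motion simulator so every stage is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    randomForest,
    e1071,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    zoo,
    optparse
Config/testthat/edition: 3
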