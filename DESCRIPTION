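Package: traymetry
Title: Visual Metrology and Size Regression for Fish-Tray Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating fish sizes from uncalibrated images of
    rectangular fish-market trays. Reads and writes a COCO-dialect instance
    annotation format extended with mouth-to-tail size polylines and tray-corner
    quadrilaterals; estimates the image-to-tray-plane homography from the corner
    points (normalized direct linear transform) and rectifies polylines, masks
    and boxes into centimetres to obtain ground-truth lengths; trains pluggable
    size regressors on pixel-level detection features under repeated k-fold
    cross-validation; evaluates predicted instance masks (IoU matching, per-class
    AP and mAP curves, confusion matrices with a missed-detection column, F1);
    plans class-balancing rotation/translation augmentation; converts lengths to
    biomass through allometric length-weight relationships; and generates
    synthetic tray scenes with known geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    polyclip,
    stats,
    utils,
    xgboost,
    ranger,
    e1071,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
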