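Package: ctrseg
Title: Automated Cardiothoracic Ratio Estimation from Chest Radiograph Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semantic segmentation of the heart and lung fields on
    posterior-anterior chest radiographs with a residual-encoder U-Net,
    geometric extraction of the cardiothoracic ratio (CTR) from the predicted
    label masks, cardiomegaly calling at CTR > 50 percent, and a complete
    segmentation / method-agreement / diagnostic evaluation layer (Dice, mIoU,
    R-squared, Bland-Altman, ROC/AUC, paired t-tests). A seeded synthetic
    chest-phantom generator with analytically known cardiac and thoracic spans
    makes every stage testable at desk scale without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jpeg,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
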