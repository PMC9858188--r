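Package: her2quant
Title: Interpretable HER2 Immunohistochemistry Scoring for Bright-Field Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Three-stage analysis of HER2 immunohistochemistry (IHC) slide
    images: tissue masking by per-channel Otsu thresholds in HSV space,
    tumor-tile detection with a pluggable patch classifier, and interpretable
    slide scoring (IHC 0/1+/2+/3+) from three computed indexes -- DAB staining
    intensity, proportion of positive cells, and circumferential-membrane cell
    ratio. Stain separation uses optical-density color deconvolution and cells
    are segmented by distance-transform watershed. Ships a synthetic IHC slide
    generator with exact per-cell ground truth, a CSCO-style rule engine, an
    interval classifier with configurable per-class thresholds, and evaluation
    utilities (ROC/AUC, precision-recall, confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    nnet,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
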