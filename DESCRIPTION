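Package: aimunet
Title: Inception-Augmented U-Net for Liver and Tumour Segmentation in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automatic liver and liver-tumour segmentation from
    abdominal computed tomography slices with an encoder-decoder convolutional
    network whose four skip connections each carry a two-stage, four-branch
    inception module. Implements the complete pipeline: synthetic abdominal
    phantom generation with known ground-truth masks, DICOM/NIfTI/PNG slice
    input and output, Hounsfield-unit windowing, histogram equalisation,
    resizing and unit normalisation, six-view paired data augmentation,
    patient-level dataset splitting, network construction with full per-layer
    parameter accounting, CPU training with Adam and binary cross-entropy,
    probability-map thresholding and volume assembly, and Dice/Jaccard/
    accuracy/precision/recall mask evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    RNifti,
    png,
    jpeg,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
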