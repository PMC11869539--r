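Package: ctnodule
Title: Lung Nodule CT Segmentation and Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated desk-scale pipeline for lung nodule analysis in
    CT-like images: synthetic phantom generation with ground-truth masks,
    Bayesian-threshold (BayesShrink) wavelet denoising, radiomic feature
    extraction (gray-level co-occurrence, shape and histogram features), a
    lightweight MobileNetV2-style encoder / U-Net decoder segmentation
    network trained with Dice loss, benign/malignant calling by an
    equivalent-diameter size rule or an RBF-kernel support vector machine,
    and confusion-matrix evaluation metrics. All stages run on reproducible
    synthetic phantoms so the full pipeline is testable without clinical
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    png,
    RNifti,
    EBImage,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
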