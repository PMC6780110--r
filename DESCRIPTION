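Package: vessnet
Title: Dual-Residual-Stream Semantic Segmentation of Retinal Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pixel-wise segmentation of retinal blood vessels in fundus
    photographs with a compact 16-convolution encoder-decoder network that
    couples inner projection and outer identity residual streams with
    index-preserving max-unpooling. Includes the deterministic three-stage
    flip/translate-crop-resize data augmentation, median-frequency
    class-balanced cross-entropy training with adaptive-moment
    optimisation, pixel-wise sensitivity/specificity/accuracy/AUC
    evaluation with error overlays, a vessel-pixel-count rule for
    visit-to-visit retinopathy screening, and a seeded synthetic fundus
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    pROC,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
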