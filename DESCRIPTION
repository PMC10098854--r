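Package: dermcgan
Title: Conditional Adversarial Segmentation of Dermoscopic Skin Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A conditional generative adversarial network (cGAN) pipeline for
    segmenting melanoma lesions in dermoscopic images. Provides artifact-removal
    preprocessing (Gaussian smoothing, grayscale morphological closing, unsharp
    sharpening), paired geometric augmentation, a U-Net generator and 70x70
    PatchGAN discriminator trained with adversarial plus L1 loss, pixel-overlap
    evaluation metrics (accuracy, Dice, Jaccard, sensitivity, specificity), and
    a seed-reproducible synthetic dermoscopy simulator (irregular lesion blobs,
    hair strokes, air bubbles with exact ground-truth masks) so the whole
    pipeline can be exercised and tested without external datasets. The neural
    network engine (convolution, transposed convolution, normalization, Adam)
    is implemented in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
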