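Package: frnetv2
Title: Lightweight Full-Resolution Convolutional Network for Retinal
    Vessel Segmentation in OCTA Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements FRNet V2, a lightweight fully convolutional network for
    segmenting blood vessels in en-face optical coherence tomography angiography
    (OCTA) images. The network keeps every feature map at the input resolution
    (no pooling or upsampling) and is built from improved recursive ConvNeXt V2
    blocks (depthwise-separable 7x7 convolutions, global response normalization,
    weight-shared recursive convolution), a hybrid channel-spatial attention
    module (DWAM) and an attention-gated feature-fusion stage (EFF). Includes a
    complete CPU training engine (Dice loss, Adam, backpropagation through all
    layers), Dice/accuracy evaluation, image/mask I/O with manifests and
    augmentation, a procedural generator of OCTA-like angiograms with exact
    ground-truth vessel masks, parameter-count reporting for all ablation
    variants, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
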