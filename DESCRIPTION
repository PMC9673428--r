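Package: scunet
Title: Serial Encoder-Decoder Segmentation Networks with Hybrid Dilated
    Convolutions for Multi-Class Tumour Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements SCU-Net, a serial dual encoder-decoder semantic
    segmentation network whose encoders use hybrid dilated convolution (HDC)
    groups and whose two sub-networks are bridged by per-layer feature
    concatenations, together with the focal Dice compound loss used to train
    it and a full segmentation-evaluation suite (mean IoU, mean pixel
    accuracy, mean precision, mean Dice, accuracy, 95th-percentile Hausdorff
    distance, average surface distance).  All network primitives (dilated and
    transposed convolutions, batch normalisation, max pooling) are provided
    with reverse-mode gradients so models can be trained with Adam under a
    cosine-annealed learning rate on a single CPU.  A synthetic phantom
    generator produces brain-like grayscale images with elliptical lesions of
    three tumour classes and matching label masks for development and testing
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
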