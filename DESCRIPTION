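Package: csfnet
Title: Multi-Color-Space Attention Fusion Networks for Ocular Disease
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements CSF-Net, an attention-guided fusion network that
    classifies ocular disease images from three complementary color-space
    representations (RGB, HSV, YCbCr). Each color space is encoded by an
    independent convolutional branch; the concatenated embeddings are refined
    by single-head scaled dot-product self-attention and classified by a
    fully connected head trained with inverse-frequency weighted
    cross-entropy. Includes a pure-R neural-network engine with manual
    backpropagation, a MobileNetV3-Small parameter-exact backbone, ablation
    variants (RGB-only, no-attention, SE/CBAM/ECA/NAM channel gates),
    stratified k-fold training with early stopping, macro metrics and
    one-vs-one macro-AUC evaluation, Grad-CAM saliency, a reproducible
    synthetic eye-image generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
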