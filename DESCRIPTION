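Package: fusionseg
Title: Dual-Decoder Fusion Networks for 3D Brain Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements FusionNet, a 3D encoder-decoder segmentation network
    that shares one VGG16-style convolutional encoder between a U-Net-style
    skip-connection decoder and a SegNet-style pooling-index decoder, joined
    by an additive, multiplicative, or concatenation fusion head. Includes
    voxelwise cross-entropy training with SGD and an exponentially decaying
    learning rate, a six-metric segmentation evaluation suite (recall,
    precision, Dice, lesion false positive rate, average volume difference,
    average symmetric surface distance), flip/rotation data augmentation with
    zero-padding to cubic inputs, and a synthetic multimodal glioma phantom
    generator so the full pipeline runs at desk scale on CPU with no external
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
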