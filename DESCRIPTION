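Package: uglseg
Title: Uncertainty-Guided Coarse-to-Fine Image Segmentation
Version: 0.1.0
Authors@R: person("UGLS", "Maintainers", email = "maintainers@uglseg.org",
    role = c("aut", "cre"))
Description: Two-stage ("coarse-to-fine") segmentation of 2-D biomedical
    images guided by boundary uncertainty. A first encoder-decoder pass
    produces a coarse per-object segmentation; morphological dilation and
    erosion with a circular structuring element turn it into a potential
    boundary region (PBR), which is Gaussian-smoothed into a boundary
    uncertainty map (BUM) and multiplied into the image as a background
    excluded image (BEI). A second pass trained on the concatenated
    BUM/BEI channels refines object boundaries. Includes a compact U-Net
    style backbone with Dice-loss RMSprop training, the standard
    segmentation metrics (Dice, Matthews correlation, sensitivity,
    Hausdorff distance), joint image/mask augmentation, fundus and
    chest-radiograph phantom generators, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
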