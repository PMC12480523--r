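Package: lungrecon
Title: Lung Tumor Segmentation, Detection and 3D Reconstruction with
    Reinforcement-Regularized Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a three-stage
    thoracic CT analysis pipeline: lung-field segmentation by a U-Net style
    generator trained as a per-pixel policy with an off-policy proximal policy
    optimization (PPO) surrogate plus a Wasserstein-style adversarial critic;
    tumor detection by a lite Mask-R-CNN-style network with classification,
    box-regression and adversarial losses; and 3D tumor reconstruction from
    ordered 2D slices by a spatial-attention transductive LSTM feeding a
    deconvolutional volume generator trained with mean absolute error plus a
    weighted adversarial term. A synthetic thorax-phantom generator supplies
    slice stacks, lung masks, tumor annotations and voxel ground truth with
    controllable class imbalance, so every loss, update rule and evaluation
    metric (IoU, Hausdorff distance, surface distance, 1-D earth mover's
    distance) can be exercised deterministically on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
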