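Package: vesselnet
Title: Retinal Vessel Segmentation with a Dual CNN-Transformer Network
Version: 0.1.0
Authors@R:
    person("Vesselnet", "Developers", email = "vesselnet@example.org",
           role = c("aut", "cre"))
Description: Segmentation of retinal blood vessels in color fundus
    photographs with a heterogeneous dual-branch neural network that
    couples a hierarchical convolutional branch with a transformer
    branch through bidirectional feature-fusion blocks.  Includes the
    TopK + Dice compound training loss, patch-based training with
    on-the-fly rotation augmentation, tiled whole-image inference,
    field-of-view restricted evaluation metrics (accuracy, sensitivity,
    specificity, F1, AUROC) with bootstrap confidence intervals, a
    seeded synthetic fundus phantom generator with exact vessel
    ground truth, and a vessel-density statistic (R_vessel) for
    longitudinal hypertensive-retinopathy quantification.  The neural
    network core (convolutions, batch/layer normalisation, multi-head
    self-attention, bilinear resampling, AdamW) is implemented in base
    R on top of BLAS matrix products, with analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
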