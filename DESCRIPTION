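Package: canopyseg
Title: Multispectral Semantic Segmentation of Forest-Pest Damage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mapping insect-induced forest canopy damage (bark
    beetle and aspen leaf miner) in Sentinel-2-like multispectral imagery
    with a nested encoder-decoder convolutional network. Provides
    vegetation-index feature stacks (21 registered indices plus the raw
    bands), grid tiling and dataset splitting, a split-attention residual
    encoder with a UNet++-style nested decoder carrying concurrent
    spatial and channel squeeze-and-excitation attention, a composite
    Dice plus label-smoothed cross-entropy objective, AdamW optimisation
    under cosine annealing with warm restarts, confusion-matrix
    evaluation metrics (per-class IoU, mIoU, FWIoU), full-scene tiled
    inference with exact stitching, and a seeded synthetic scene
    generator for end-to-end testing. The network runs on a small
    reverse-mode automatic-differentiation engine over dense arrays
    included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
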