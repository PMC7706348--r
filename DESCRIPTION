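Package: flowerseg
Title: Small Bright-Target Segmentation in Canopy Images by Combining
    Otsu Binarization with a Patch-Based CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies small bright targets (such as coffee flowers) in
    ground-based RGB time-lapse images of plant canopies. A from-scratch
    Otsu binarization recovers precise target contours, a patch-based
    convolutional neural network classifier trained on 31x31 blocks
    suppresses bright background false positives, and the pixel-wise
    intersection of the two masks yields the final segmentation. Includes
    SLICO-style superpixel oversegmentation with region merging for
    building training sets and ground truth, pixel-level evaluation
    (recall, precision, F1/Dice, IoU), a seeded synthetic canopy scene
    generator with ground truth for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    jpeg,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
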