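Package: tumorseg
Title: Brain Tumor Segmentation with an Attention U-Net and Physical Area
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments brain tumors in 2-D MRI slices and converts segmented
    masks into physical areas (mm^2) using pixel-spacing metadata. Implements
    classical intensity-threshold baselines (fixed rule, iterative isodata,
    Otsu), a family of U-Net encoder-decoder segmentation networks - a classic
    U-Net, a VGG19-encoder U-Net, and a lightweight VGG19 U-Net whose decoder
    uses depthwise separable convolutions refined by convolutional block
    attention (CBAM) - together with the full training protocol (soft dice
    loss, Adamax, early stopping), overlap metrics (accuracy, Dice, IoU), and
    trial statistics. Networks are built on a self-contained reverse-mode
    automatic differentiation engine, so the package has no external deep
    learning dependency. A synthetic MRI phantom generator with analytic
    ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
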