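Package: camuvision
Title: Image-Based Estimation of Ascorbic Acid in Camu-Camu Fruit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive estimation of ascorbic acid (vitamin C) content
    of camu-camu (Myrciaria dubia) fruit from RGB images. Detects fruit
    regions on a neutral background, assigns one of four ripeness stages,
    converts pixel areas to physical areas with a fixed camera calibration,
    predicts pulp mass with a calibrated quadratic area-maturity model, and
    scales certified stage-specific laboratory concentrations by the
    estimated-to-reference mass ratio. Includes a seeded synthetic-scene
    generator with exact ground truth, COCO-style annotation I/O, and
    evaluation utilities (MAPE, detection precision/recall/F1, stage
    confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
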