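Package: plugtray
Title: Machine-Vision Grading of Potted Seedlings in Plug Trays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies healthy potted seedlings in plug-tray images. Provides
    green/red color-index preprocessing of RGB tray images, two-threshold
    maximum-entropy segmentation optimized by a genetic algorithm (with an
    exhaustive-search oracle), block-matching 3D-transform (BM3D) denoising of
    the segmented mask, per-cell leaf-area measurement, and a four-class health
    grading (healthy, sub-healthy, poor, empty) with tray-cell coordinates for
    a transplanting robot. Includes a synthetic tray-image generator with
    ground truth so the whole pipeline is testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
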