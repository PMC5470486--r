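Package: rowsense
Title: Optical Plant Detection and Inter-Plant Spacing for Row Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detection and along-track localization of individual crop plants
    from ground-platform optical sensor logs: an infrared light-beam plus
    wheel-encoder stem detector, a side-view LiDAR point-cloud chain
    (pose transformation, box-grid downsampling, MSAC ground-plane removal,
    k-means plant clustering with cluster-count reduction, and three stem
    localization methods), and an image/odometry stem validation chain.
    Includes detection-matching and spacing-accuracy metrics, synthetic row
    generators emulating the field platforms, delimited-text and PLY/XYZ
    point-cloud input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
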