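Package: htoplan
Title: Automatic Correction-Angle Planning for High Tibial Osteotomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic preoperative planning of the opening-wedge high
    tibial osteotomy correction angle from standing long-leg anteroposterior
    radiographs, following the Miniaci graphical method. Detects the femoral
    head centre with a circular Hough transform, the inner and outer knee
    (tibial plateau) points with Active Shape and Active Appearance Models
    trained from landmark annotations, and the talus border points by
    morphological segmentation of the tibiotalar joint space; combines them
    into the mechanical axis, Fujisawa point, hinge point and signed
    correction angle. Includes a synthetic long-leg radiograph phantom
    generator with exact ground truth, ingestion of darknet-format region
    of-interest boxes, and agreement statistics (two-way intraclass
    correlation with F-based confidence intervals, Bland-Altman limits of
    agreement, skew-normal fits of angle distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
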