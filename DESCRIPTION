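Package: fourchamber
Title: Fetal Four-Chamber-View Biometry from Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of the fetal cardiac axis (CAx) and
    cardiothoracic ratio (CTR) from multi-class segmentation masks of the
    four-chamber echocardiographic view. Implements the full measurement
    pipeline: skeletonization of the interventricular septum with longest-path
    pruning and total-least-squares line fitting, the thoracic anteroposterior
    axis from mask centroids, contour extraction and direct least-squares
    ellipse fitting for the cardiothoracic area ratio, per-label Dice/IoU
    segmentation scoring, and rater-agreement statistics (normality-gated
    paired tests, Bland-Altman limits of agreement, ICC(2,1)). Includes a
    parametric synthetic fetal-thorax phantom generator with known ground
    truth for validating the geometry without clinical data, plus command-line
    tools for batch measurement, evaluation and agreement analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    RNifti,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
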