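Package: wallplex
Title: Whole-Slide Multiplex Immunohistochemistry Analysis of the Vessel Wall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell spatial analysis of whole-slide multiplex
    immunohistochemistry (mIHC) data from the aortic wall. Provides
    flow-cytometry-like phenotype gating with adaptive thresholds for
    gradually expressed markers, layer-stratified quantification
    (intima/media/adventitia) of immune cell composition, detection of
    tertiary lymphoid structures as contact-connected mixed T/B-cell
    clusters with zone and germinal-center classification, nearest-neighbor
    distance analysis between phenotypes, and the nonparametric statistical
    battery used for cohort comparison. Includes a calibrated synthetic
    whole-slide generator with known ground truth that emulates
    post-segmentation single-cell tables, so the entire pipeline can be run
    and validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
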