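Package: isletscope
Title: Islet Mask Morphometry, Expert Review Sets and Contour Agreement Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of pancreatic islet segmentation by a
    panel of experts. Reads class-coded segmentation masks of dithizone-stained
    islet micrographs, labels individual islets, converts pixel areas to
    equivalent diameters, 50 um size categories and islet-equivalent (IE)
    volumes under the spherical model, and extracts islet boundary contours for
    overlay and per-islet cropped displays. A seeded selection engine builds
    review sets by drawing random images and size-stratified random islets, or
    accepts manual picks. Expert-drawn separation lines and contours are scored
    against templates by symmetric average line distance with a 2 px accuracy
    rule, and by contour-derived volume relative error and replicate
    coefficient of variation. Expert opinions (image quality classes, islet
    true/false verdicts, graphical edits) are validated, tallied and rendered
    into anonymized consensus reports. Includes System Usability Scale scoring
    with curved grading and a synthetic scene generator so the whole pipeline
    is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
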