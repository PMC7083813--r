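Package: lesionmap
Title: Mapping and Quantification of Cortical Lesions on an Unfolded
    Mouse Cortex Template
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps slice-wise cortical lesion measurements taken from
    histological sections or magnetic resonance images onto a
    two-dimensional unfolded template of the mouse cerebral cortex, and
    quantifies the absolute (mm^2) and fractional damage per
    cytoarchitectonic region.  Provides SVG template parsing with cubic
    Bezier flattening (de Casteljau subdivision), per-slice shrinkage
    normalization against atlas cortical surface lengths, linear and
    centripetal Catmull-Rom contour interpolation, polygon Boolean
    quantification, time-series lesion evolution with contour
    transitions, CSV/TIFF/PDF/PNG export, a synthetic template
    generator, and a batch-capable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    polyclip,
    png,
    readxl,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    zip
Suggests:
    sp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
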