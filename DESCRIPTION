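Package: cellAFM
Title: Virtual Image-Guided Atomic Force Microscopy for Single-Cell
    Mechanics in Co-Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hardware-free workbench for image-recognition-guided atomic
    force microscopy (AFM) force spectroscopy on high-density co-cultured
    cells. Generates synthetic co-culture scenes (paired bright-field and
    two-channel fluorescence images with ground truth), annotates and
    detects cells and the spherical AFM probe from images, plans
    pixel-to-stage probe moves, simulates indentation and single-cell
    force spectroscopy (SCFS) force curves from known mechanical truth,
    extracts Young's moduli by Hertz-model fitting and adhesion forces
    from retract curves, and summarises cell-type populations with
    Gaussian fits. Designed for validating force-curve analysis by
    parameter recovery on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
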