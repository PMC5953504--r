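Package: hsafmCME
Title: Quantification of Clathrin-Mediated Endocytosis in Hybrid HS-AFM/Confocal Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying clathrin-mediated endocytosis (CME) from hybrid
    high-speed atomic force microscopy (HS-AFM) and confocal fluorescence time-lapse
    movies: co-registration of the AFM scan area with the optical frame via the
    probe-origin procedure, per-frame detection and gap-closed tracking of membrane
    pits, section-profile morphometry with tip-curvature correction, fluorescence
    phase segmentation (growing/stable/closing), classification of terminal closing
    motions (capping, two-step, re-opening), drift-corrected mean-square-displacement
    diffusion estimation, and protein-timing statistics. A first-class synthetic-data
    generator renders paired AFM height and fluorescence movies with ground truth,
    emulating pit geometry, lifecycle kinetics, tip convolution, scan artifacts and
    shot/read noise, so every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, ImageImport, CellBiology, Visualization
RoxygenNote: 7.3.3
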