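Package: scifidose
Title: Single-Projection Reconstruction of Small Circular Radiotherapy
    Fields from Scintillating-Fiber Detector Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance toolkit for small static photon fields shaped
    by stereotactic cone collimators, measured with a multi-layer ribbon of
    scintillating plastic fibers read out by a camera.  The ribbon records a
    one-dimensional projection of the two-dimensional dose field; for
    rotationally symmetric cone fields this projection is inverted into a
    stack of concentric disks by a non-negative Simultaneous Iterative
    Reconstruction Technique (SIRT), regularized by a fixed iteration cap.
    Provides a synthetic-data generator (ground-truth dose fields, fiber-level
    forward projection, camera rendering, noise injection), image
    preprocessing (3x3 median filtering, 5x5 binning, axis integration,
    background subtraction, resampling, symmetric folding), the disk-stack
    reconstruction, and beam metrics (field center, FWHM, 20-80% penumbra,
    relative output factors), plus TIFF/CSV/JSON input-output and an
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
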