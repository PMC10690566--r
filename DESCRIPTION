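Package: specktools
Title: Quantitative Single-Molecule Localization Analysis of Inflammasome ASC Specks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying endogenous ASC speck assembly from
    single-molecule localization microscopy (dSTORM/DNA-PAINT) data:
    localization-table and ROI input/output, affine two-channel
    registration from fiducials, super-resolution rendering, DBSCAN and
    Ripley's K cytoplasmic cluster statistics, speck morphometrics
    (radius of gyration, eccentricity, density), filament diameter
    measurement by Gaussian cross-section profiling with label-size
    correction, day-to-day calibration, pseudo-time ordering of speck
    assembly with center-of-mass alignment and sum projections, and a
    ground-truth synthetic scene generator emulating labeling-probe size,
    affinity and steric-exclusion artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
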