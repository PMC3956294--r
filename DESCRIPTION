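Package: nodescale
Title: Surface-Area Sensing by Cortical Node Proteins in Fission Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cell-size sensing by the cortical
    node protein cdr2p in fission yeast. Provides closed-form and numeric
    quasi-steady-state solutions of uniform-cortex and
    modification-intermediate accumulation models, a one-dimensional
    reaction-diffusion solver for cortical and nodal densities,
    spherocylinder geometry and contour-based surface-area/volume
    measurement, fluorescence-profile quantification (exponential tip
    gradients, Gaussian node bands, medial-band intensities, node
    detection, FRAP turnover, molecule-count calibration),
    division-size statistics (Jensen-Shannon distance, Monte-Carlo
    slope-robustness tests, matched-subset selection), and seeded
    synthetic-data generators that emulate the corresponding microscopy
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
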