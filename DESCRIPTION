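Package: gcclutch
Title: Molecular-Clutch Simulation and Single-Molecule Trajectory Analysis
    for Neuronal Growth Cones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the molecular clutch between adhesion receptors
    and retrograde actin flow in neuronal growth cones. Provides a stochastic
    simulator of actin-molecule dynamics in a virtual two-dimensional conical
    growth cone with transient coupling to substrate adhesions, a
    single-particle-tracking analysis pipeline (mean squared displacement,
    anomalous-exponent and directed-motion fits, motion and mobility
    classification), super-resolution nanodomain rendering and segmentation,
    FRAP diffusion/reaction curve fitting, and optical-tweezers bead-track
    analysis with Stokes-drag trap calibration. Synthetic-data generators for
    every stage allow the whole pipeline to be exercised without microscopy
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
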