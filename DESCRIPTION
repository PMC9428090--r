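Package: quietmr
Title: Simulation, Reconstruction and Evaluation of Quiet MPRAGE Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for studying quiet T1-weighted MPRAGE
    acquisitions that replace fast whole-body gradient switching with a
    resonant 20 kHz silent z-gradient insert. Provides extended phase graph
    (EPG) simulation of MPRAGE signal and grey-white matter contrast with
    flip-angle matching between protocol variants, gradient waveform and
    k-space trajectory construction (slew-limited trapezoids, silent
    sinusoidal readout encoding, CAIPI sampling patterns), iterative
    conjugate-gradient SENSE reconstruction for Cartesian, CAIPI and
    oscillating (wave) trajectories, a numerically generated multi-coil
    brain phantom, A-weighted sound-level metering and acoustic prediction
    through a configurable gradient-to-pressure transfer model, image SNR
    and CNR metrics, and the exact paired Wilcoxon signed-rank test and
    Cohen's kappa used to analyse rating tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
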