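Package: aortaflow
Title: Image-Based Aortic Hemodynamics: Segmentation, Boundary Models and
    Wall-Shear Indices
Version: 0.1.0
Authors@R:
    person("Aortaflow", "Developers", email = "aortaflow@example.org",
           role = c("aut", "cre"))
Description: Tools for the image-to-hemodynamics analysis chain used in
    patient-specific studies of aortic dissection. Covers minimally
    supervised lumen segmentation of CT-like image stacks (histogram
    equalization, adaptive threshold smoothing, Otsu binarization,
    Moore-neighbor boundary tracing with Jacob's stopping criterion, and
    point-cloud assembly), inlet and outlet boundary-condition models
    (harmonic waveform fitting, the three-element Windkessel with explicit
    Euler integration and parameter estimation, k-epsilon turbulence
    initialization), wall-shear and vortex post-processing (WSS, WSF,
    TAWSS, OSI, y+, Q-criterion, turbulence intensity, backflow
    diagnostics), and the scalar verification statistics used for cycle
    convergence, mesh sensitivity and per-outlet flow distribution.
    Ships a synthetic-data module that generates CT phantoms with exact
    ground truth and analytic pulsatile pipe-flow fields (Poiseuille and
    Womersley) with closed-form wall shear, so the whole chain is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
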