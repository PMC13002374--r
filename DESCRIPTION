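Package: cardiomod
Title: Monodomain Cardiac Tissue Simulation of Inflammatory Electrophysiological Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates electrical activity of two-dimensional cardiac tissue
    with the monodomain reaction-diffusion model, coupling a spontaneously
    beating human induced pluripotent stem cell derived cardiomyocyte
    (hiPSC-CM) ionic model and an adult human atrial ionic model to a
    finite-difference diffusion solver. Inflammatory electrophysiological
    remodeling is represented as circular tissue patches carrying
    multiplicative downregulation of the fast sodium current, the
    sodium-potassium pump current, and tissue conductivity. Includes
    conduction-velocity calibration, pacing and stress-pacing protocols,
    beat-irregularity and conduction-heterogeneity statistics, action
    potential morphology metrics, detection of pacing-induced sustained
    (fibrillation-like) activity, and seeded synthetic-readout generators
    for testing the analysis statistics against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
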