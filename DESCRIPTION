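Package: ssvepscreen
Title: Genotype Classification from Steady-State Visually Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for genotyping Drosophila from
    spatiotemporal profiles of steady-state visually evoked potentials (SSVEPs).
    Generates seeded synthetic cohorts of per-trial voltage recordings over an
    8 x 8 spatial-by-temporal frequency stimulus grid, extracts second-harmonic
    response amplitudes by coherent (phase-sensitive) frequency-domain
    averaging, classifies individual animals with shrinkage-regularized linear
    discriminant analysis scored by leave-one-out cross-validation and
    stratified bootstrap significance, and visualizes genotype similarity by
    nonmetric multidimensional scaling with convex-hull cluster separation.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    mgcv,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
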