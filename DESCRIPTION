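Package: flagpower
Title: Flagellar Beat Waveform Analysis and Energy Budgets from Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement chain from dark-field movies of head-tethered,
    planarly beating sperm to per-beat-cycle flagellar energy budgets.
    Extracts single-pixel centerlines from TIFF stacks, builds smooth
    tangent-angle waveforms with a rigid-head fit and a C2-constrained
    Chebyshev least-squares fit of the tail, performs proper orthogonal
    decomposition in Chebyshev coefficient space (C-POD), evaluates
    resistive-force-theory hydrodynamics near a wall and Kelvin-Voigt
    internal moments for a soft internally driven Kirchhoff rod, and closes
    the energy balance to obtain hydrodynamic, passive-internal and motor
    dissipation together with the motor power input. Includes a synthetic
    movie generator for end-to-end validation, beat-cycle segmentation in
    shape-coefficient phase space, and pooled cycle statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    pracma,
    tiff,
    EBImage,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
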