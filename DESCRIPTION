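Package: mwablate
Title: Finite-Element Simulation of Microwave Tumor Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled electromagnetic-thermal finite-element simulator of
    microwave ablation of liver tumors with a multi-slot coaxial antenna.
    Solves the axisymmetric frequency-domain Helmholtz equation for the
    antenna field, converts it to a specific absorption rate, and advances
    a transient bioheat model (Pennes, local-thermal-equilibrium, or
    local-thermal-non-equilibrium porous media) with temperature-dependent
    dielectric properties, water-content-driven effective heat capacity or
    enthalpy-spike vaporization, perfusion shutdown, and an Arrhenius
    thermal-damage integral. Reports lethal-isotherm and iso-damage
    contours, tumor-coverage metrics, power sweeps, and an optimal-power
    bisection search on synthetic ellipsoidal tumors or imported
    triangulated tumor surfaces.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
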