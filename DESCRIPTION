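Package: angioadapt
Title: Simulation of Sprouting Angiogenesis with Structural Adaptation and
    Pruning in Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of microvascular network formation in a
    thin two-dimensional tissue. Couples steady network hemodynamics (nodal
    pressure solve, empirical in-vivo blood viscosity, red-cell phase
    separation at bifurcations) to Green's-function oxygen transport with
    Michaelis-Menten tissue consumption, a reaction-diffusion VEGF field
    released by hypoxic tissue, stochastic VEGF-dependent vessel sprouting
    with filopodia-mediated homing, shear/pressure/metabolic/conducted
    structural diameter adaptation, tension-induced node migration, and
    pruning. Starting from a sparse seed skeleton, the model grows stable,
    hierarchical, space-filling networks and supports mechanism-knockout
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
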