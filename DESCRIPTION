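Package: stentsim
Title: Multiscale Agent-Based Simulation of In-Stent Restenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale three-dimensional multiscale simulator of
    neointimal growth in stented coronary arteries. Vessel walls are
    represented as off-lattice agents (smooth muscle cells, elastic
    laminae, extracellular-matrix blobs, stent material) interacting as
    elastic spheres connected by springs and relaxed to mechanical
    equilibrium with a variable-step fourth-order Runge-Kutta
    integrator. Steady blood flow through the evolving lumen is solved
    with a D3Q19 lattice-Boltzmann method and wall shear stress is
    mapped back onto lumen-facing agents. An hourly biological ruleset
    drives smooth muscle cell phenotype switching, proliferation,
    contact inhibition, shear-and-endothelium growth arrest, stochastic
    re-endothelialisation and stochastic production of loose
    proteoglycan-rich extracellular matrix. The package also provides
    histomorphometry-style cross-section metrics (per-strut neointimal
    thickness, signed and relative neointimal area) and parametric
    generators for stents and straight or toroidally curved vessels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
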