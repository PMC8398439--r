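Package: transwellr
Title: Simulation and Optimization of Transwell Dissolution Tests for
    Orally Inhaled Drug Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic simulation of the Transwell dissolution test used
    to characterize orally inhaled drug products. Couples bin-wise
    Nernst-Brunner dissolution of a polydisperse particle population
    (built from cascade-impactor stage depositions) to first-order membrane
    diffusion in a volume-limited two-compartment system with discrete
    sampling-and-replacement events. Includes hydrostatic donor/receptor
    volume matching, Weibull mean-dissolution-time fitting, f1/f2
    dissolution-profile similarity metrics, estimation of membrane
    permeability and of the Nernst-Brunner correction factor from observed
    transfer profiles, and scripted scenario sweeps (solubility, volumes,
    sampling volume, particle size, dose) for assay optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
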