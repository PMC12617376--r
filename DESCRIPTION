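Package: dcsfit
Title: Analytical Model Fitting and Simulation for Diffuse Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Forward simulation and inverse-model fitting for continuous-wave
    diffuse correlation spectroscopy (DCS) measurements of cerebral blood flow.
    Provides layered slab head models, closed-form and Hankel-transform
    solutions of the correlation diffusion equation (semi-infinite, two-layer,
    three-layer), a correlation Monte Carlo photon-transport generator with
    per-layer momentum-transfer and pathlength tallies, a multi-tau correlator
    noise model, bounded derivative-free fitting strategies (early time lag
    range, single- and multi-distance), and blood-flow-index sensitivity and
    crosstalk metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
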