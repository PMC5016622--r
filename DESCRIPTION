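Package: canopyray
Title: Canopy Photosynthesis from 3D Plant Architecture and Light Ray Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates whole-plant and canopy photosynthesis of greenhouse
    sweet pepper (Capsicum annuum) by combining a parametric 3D plant
    reconstruction, Monte Carlo ray tracing of direct and diffuse light with
    leaf reflectance and transmittance, per-layer parameterization of the
    Farquhar-von Caemmerer-Berry (FvCB) leaf model from light-response and
    A/Ci gas-exchange curves, and half-hourly integration of layer
    photosynthesis to the plant scale. Includes closed-chamber CO2 drawdown
    inversion for validation and synthetic-data generators with known ground
    truth for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
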