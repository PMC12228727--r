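Package: corneauv
Title: Monte Carlo Tissue Optics of the Cornea in the Far UV-C Band
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Monte Carlo photon transport in layered corneal models
    (tear film, epithelium, stroma) over the 200-300 nm band, inverse Monte
    Carlo estimation of absorption and reduced scattering coefficients from
    integrating-sphere reflectance and transmittance of thin tissue sections,
    penetration-depth and DNA-damage-depth analytics, and a synthetic-data
    generator emulating the spectral structure of corneal tissue so every
    stage is testable without laboratory measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
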