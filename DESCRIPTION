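Package: otos
Title: Tissue Oximetry from Integrating-Sphere Diffuse Reflectance
Version: 0.1.0
Authors@R:
    person("OTOS", "Maintainers", email = "otos@example.org", role = c("aut", "cre"))
Description: Recovers tissue absorption spectra from integrating-sphere
    diffuse-reflectance measurements by inverse adding-doubling, classifies
    skin by the 630-700 nm melanin slope of the absorption spectrum, and
    computes tissue oxygen saturation (StO2) from a two-wavelength
    oxy/deoxy-hemoglobin solve. Includes a forward adding-doubling solver
    for the radiative transfer equation in turbid slabs, a Monte-Carlo
    photon-transport oracle for validation, a synthetic measurement
    generator (palm-skin reflectance and stepped-pressure occlusion
    series), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
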