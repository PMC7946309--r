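Package: pedidose
Title: Monte Carlo Dosimetry of Dispersed Dose in Pediatric Photon and
    Proton Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo particle transport through stylized
    pediatric phantoms (newborn to 15 years) for comparing out-of-field
    organ doses in 6 MV photon and 240 MeV proton radiotherapy. Builds
    age-parameterized quadric-surface phantoms, transports photons with a
    track-length kerma estimator and protons with condensed-history
    stepping, accumulates per-organ absorbed dose per primary particle
    with Monte Carlo uncertainty, derives dispersed-dose conversion
    coefficients F = Dd/Dt at five irradiation positions, runs a
    hyper-fractionated (CHART-style) 54 Gy left-lung case study, and
    performs a paired photon-versus-proton comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
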