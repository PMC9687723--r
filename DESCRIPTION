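Package: suspeis
Title: Low-Frequency Impedance Spectroscopy of Particle and Cell Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of 10-1000 Hz electrical impedance spectra of
    particles and non-adherent cells suspended in an electrolyte, where
    electrical double layers dominate. Implements an equivalent-circuit
    forward model with constant phase elements, the unified effective
    capacitance, the dispersed medium index (a normalized magnitude
    spectrum), bounded Levenberg-Marquardt circuit fitting, calibration of
    either response against suspension concentration,
    Gouy-Chapman-Stern double-layer capacitances, and seeded synthetic
    spectrum generation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
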