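Package: patchtension
Title: Membrane Tension and Mechanosensitive Channel Gating Analysis for
    Pressure-Clamp Patch Imaging
Version: 0.1.0
Authors@R:
    person("Patchtension", "Developers", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline linking patch-pipette membrane
    geometry to mechanosensitive (Piezo1-type) ion-channel activity.
    Detects the membrane dome in pipette images by line-scan intensity
    minima, fits a circle to obtain the radius of curvature, converts
    applied pressure to lateral membrane tension via Laplace's law, and
    fits Boltzmann activation and exponential recovery-from-inactivation
    models to pooled, binned current responses.  A synthetic-data module
    renders phantom patch images and simulates pressure-clamp current
    sweeps with known ground truth so that every stage of the pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
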