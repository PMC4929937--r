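Package: sensquad
Title: Quadrate Sampling and Phylogenetic Comparative Analysis of Scale
    Sensilla
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies dome-shaped mechanosensory scale sensilla on labelled
    images of snake head scales using unbiased counting-frame quadrate
    sampling (numerical density, mean sensillum size and percentage
    coverage), and analyses species means in a phylogenetic framework:
    log-log allometric regression on phylogenetic independent contrasts with
    F tests, and Brownian-motion ancestral-state reconstruction of sensilla
    coverage on a time-calibrated tree. Includes simulators for hard-core
    disc scenes, Yule trees and Brownian traits that provide ground truth
    for every stage, and a command-line pipeline for deterministic re-runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
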