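Package: puffwave
Title: Hybrid Stochastic-Deterministic Simulation of Calcium Puffs and Waves
    from an IP3 Receptor Cluster
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates calcium release from a single cluster of inositol
    1,4,5-trisphosphate receptor (IP3R) channels by coupling a modified
    DeYoung-Keizer Markov gating model to deterministic calcium/buffer
    reaction-diffusion in a cuboidal cytosolic domain with channel, SERCA
    and leak fluxes across the ER membrane. Provides a full-grid
    finite-volume solver, a fast calibrated reduced-domain mode for
    long-trace statistics, a replay mode driving the fields with prescribed
    channel gating, and an event-analysis stage that detects collective
    release events, classifies them into puffs and waves, and computes
    duration, activatable-channel, event-shape, inter-wave-interval and
    inter-wave-phase statistics as functions of IP3 concentration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
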