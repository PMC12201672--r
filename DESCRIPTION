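Package: engramsim
Title: Biophysical Spiking-Network Simulation of Sleep-Dependent Memory
    Consolidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based Hodgkin-Huxley network simulator in which the
    slow M-type potassium current acts as a proxy for state-dependent
    acetylcholine levels during NREM and REM sleep.  Implements additive,
    bounded spike-timing-dependent plasticity with population-specific rates,
    construction of single- and two-memory engram networks, sleep-cycle
    stimulation protocols, and a spike-train analysis suite built around the
    average-minimal-distance (AMD) functional-connectivity z-score, including
    engram activation, segregation and overlap statistics and a paired
    NREM/REM bout comparison.  Synthetic spike-train fixtures make every
    statistic testable without running the full simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
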