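Package: replicomb
Title: Single-Molecule DNA Combing Analysis of Replication Origin Firing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of replication origin firing on combed
    single DNA molecules from fission yeast. Provides a stochastic S-phase
    simulator (origin firing per Mb of unreplicated DNA, bidirectional forks,
    pulse/chase labeling, combing measurement noise), generators for clustered,
    uniform and rDNA-array origin placements, per-molecule track measurements
    (origin calls, inter-origin distances, moving-average replication
    profiles), survival-curve statistics with two-regime exponential
    decomposition and Monte-Carlo Lilliefors exponentiality testing,
    replication-cluster calling, and pulse/chase fork-velocity and
    firing-rate kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
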