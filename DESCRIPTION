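Package: loopkit
Title: Single-Molecule Analysis of DNA Loop Extrusion by the Rad51-Rad54
    Presynaptic Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative toolkit for single-molecule studies of DNA loop
    extrusion by the Rad51-Rad54 presynaptic complex. Provides a stochastic
    two-motor loop-formation-rate simulator, extensible worm-like-chain
    polymer mechanics, magnetic-tweezer trace analysis (smoothing, baseline
    statistics, threshold event calling, exponential lifetime fitting,
    hat-curve buckling slopes), optical-trap force-extension decomposition
    (sawtooth loop sizing, rupture forces, clamp velocities, maximum force
    output), torque-plot construction with linear stall-torque
    extrapolation, and D-loop capture (DLC) quantification from qPCR
    crossing points. Seeded synthetic-data generators emulate every input
    so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
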