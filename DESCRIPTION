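Package: hemoclust
Title: Stochastic Simulation and Quantification of Crystal Cell
    Differentiation in Sessile Hemocyte Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based discrete-time simulation of Drosophila larval
    sessile hemocyte clusters in which crystal cells arise by
    Notch/Serrate contact-dependent transdifferentiation of
    plasmatocytes; a synthetic two-channel time-lapse microscopy
    generator with ground-truth event logs; an automated quantification
    pipeline (nucleus detection, track linking, division and induction
    calling, rate estimation, contact scoring, flow-cytometry-style
    gating, hemocytometer conversion); the discrete-time extrapolation
    recurrence linking per-window differentiation proportions to
    population increases; and normality-gated statistical comparison
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
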