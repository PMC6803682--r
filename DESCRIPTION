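Package: dvmopt
Title: Optimal Diel Vertical Migration Strategies in Stage-Structured
    Zooplankton Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding evolutionarily optimal diel vertical migration
    (DVM) strategies of stage-structured zooplankton. Vertical profiles of
    food, metabolic cost, visual-predation risk and unfavorable-zone mortality
    are mapped through piecewise-linear daily depth trajectories to
    stage-specific life-history rates; evolutionary fitness is the dominant
    root of the characteristic equation of a three-stage von Foerster
    population model. The package provides multistart Nelder-Mead trajectory
    optimization, parameter scans, and a direct competing-strategies cohort
    simulator that verifies the fitness ranking dynamically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
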