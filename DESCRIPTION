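Package: hexsearch
Title: Egocentric and Grid-Like Coding Analyses for Mental Search in 2D
    Feature Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design, simulate and analyse goal-directed "mental
    search" experiments in two-dimensional conceptual feature spaces.
    Provides a constrained trial generator for the two-context recall
    task (balanced egocentric goal-angle conditions and quadrants, with a
    decorrelated goal-distance covariate), a synthetic-data module that
    plants egocentric tuning with log-recency adaptation, rotation-
    correspondent quadrant patterns, and hexadirectional (grid-like)
    direction codes into HRF-convolved BOLD time series, and the
    matching analysis pipelines: adaptation GLMs with parametric
    modulators and control variants, cross-context nearest-neighbour
    decoding with searchlight and MDS, 180-degree rotation similarity of
    quadrant patterns, grid representational similarity analysis with
    control symmetries, goal-proximity modulation of the grid signal,
    gaze-egocentric correlations, behavioural metrics and group-level
    inference. Results are returned as tibbles with broom-style tidy()
    and glance() methods and ggplot2 autoplot() displays.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
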