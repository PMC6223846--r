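Package: zebralearn
Title: Automated Analysis of Appetitive Olfactory Discrimination Learning
    in Adult Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify appetitive olfactory conditioning of adult
    zebrafish from 3D swimming trajectories. Provides a synthetic trajectory
    and two-view video generator for validation, centroid tracking of paired
    orthogonal camera views, extraction of six behavioral parameters (swimming
    speed, relative z-position, reward-zone residence, surface-sampling events,
    distance to the water inflow, and spectral circling index), a baseline- and
    reference-window normalized zeta-score transform, Stouffer-style composite
    appetitive scores with optional covariance weighting, trial-resolved
    learning curves, a discrimination score with rank statistics, and the
    pre-odor window-shift and unpaired negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    zoo,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
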