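Package: spheroscale
Title: Metabolic Scaling of Cell-Laden Spheroids with Correlated Mass and
    Metabolism Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates populations of cell-laden spheroids with log-normally
    distributed radii and Gaussian single-cell oxygen consumption rates,
    solves the stationary spherically symmetric oxygen reaction-diffusion
    problem with Michaelis-Menten (or Hill) kinetics per spheroid, and
    estimates allometric scaling exponents by collapsing marginal and joint
    mass-metabolism probability distributions using residual-based and
    distance-based functionals. Includes k-sample Anderson-Darling and
    Henze-Zirkler statistical validation, iterative size-window
    identification with viability classification, and meta-experiments
    (minimum sample size, variability sweeps, parameter sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
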