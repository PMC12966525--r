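Package: perankle
Title: Quasi-Static Ligament Tension Simulation of Pronation-External
    Rotation Ankle Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A passive rigid-body model of the human ankle (tibia, fibula,
    talus and a rigid hindfoot unit) with tension-only piecewise-elastic
    ligaments, driven quasi-statically through a pronation-external-rotation
    (PER) injury protocol. Joints are stiff penalty constraints so ligament
    tensions and joint reaction forces are obtained concurrently from a
    single energy minimisation at each prescribed external-rotation step.
    Includes a synthetic-anatomy generator for plausible ankle geometry, a
    bounded least-squares calibration routine that fits ligament material
    parameters to published tension anchors, a packaged calibrated reference
    model, and tooling to extract tension traces, plateau statistics and
    emergent joint kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
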