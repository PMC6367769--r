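Package: cprkinemat
Title: Kinematic Analysis of Rescuers Performing Continuous Chest Compressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the body kinematics of a kneeling rescuer
    performing continuous chest compressions on a manikin. Simulates the two
    measurement streams of such an experiment (inertial body-sensor landmark
    trajectories and the manikin compression-depth log), synchronizes them by
    cross-correlation, extracts joint flexion angles, trunk inclination,
    compression-axis deviation and postural-sway metrics (path length, 95
    percent prediction-ellipse area) of the C7-Th1 sensor, decomposes the
    compression force by deviation angle, assembles per-minute feature tables
    with depth-threshold grouping, and fits standardized multiple regressions
    of compression depth on the kinematic predictors. Includes a feature-level
    generator calibrated so that the population standardized coefficients and
    explained variance match a chosen target, for parameter-recovery studies.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
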