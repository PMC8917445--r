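Package: swimkin
Title: Swimming Kinematics and Fast-Start Classification for Petri-Dish
    Video Assays of Larval Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A measurement and classification pipeline for dorsal-view
    high-speed video assays of single larval fish in Petri-dish arrays:
    silhouette segmentation and centre-of-mass tracking per dish,
    Savitzky-Golay speed and acceleration estimation, fast-start escape
    response detection via a bimodal-histogram valley threshold with a
    seven-frame window rule, robust quantile-mean performance summaries,
    feeding-session segmentation with supply-disturbance exclusion, and a
    clustered-bootstrap slope estimator for maternal-treatment cohort
    designs. Includes a seeded synthetic-data generator (trajectories,
    rendered frame sequences, feeding sessions, offspring cohorts) so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    signal,
    EBImage,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
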