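Package: scaption
Title: Dynamic Simulation of Subacromial Impingement During Scapular-Plane
    Elevation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the bony morphology of the lateral acromion
    and the greater tuberosity narrows the subacromial space during scaption
    (arm elevation in the scapular plane). Provides triangle-mesh input/output
    and exact mesh-to-mesh minimum-distance queries (brute-force and
    bounding-volume-hierarchy accelerated), sphere fitting of the humeral
    head, International Society of Biomechanics bone coordinate systems,
    three-dimensional measurement of the critical shoulder angle (CSA) and
    greater tuberosity angle (GTA) in the corrected coronal plane, an
    incremental scaption simulator that records the minimum acromio-humeral
    distance at each degree of elevation and derives the impingement-free
    range of motion (IF-ROM) under a 6 mm threshold, a parametric synthetic
    shoulder generator with closed-form distance oracles, and the cohort
    statistics (group comparisons, Pearson/Spearman correlation battery,
    intraclass correlation) used to relate CSA, GTA and their sum to IF-ROM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
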