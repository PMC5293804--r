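Package: reachgrasp
Title: Simulation and Analysis of Reach-to-Grasp Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the kinematics of reach-to-grasp movements
    recorded with optical or electromagnetic motion capture. The package
    simulates three-marker (wrist, index, thumb) reaching and grasping
    trials with controllable ground truth, extracts the classical
    transport and grip parameters (reach time, velocity peak amplitude
    and latency, normalized latency, grasp time, maximal finger aperture
    and its latency) using displacement- or velocity-threshold movement
    segmentation, applies trial-rejection and participant-exclusion
    rules, and runs the within-subject inference layer: repeated-measures
    ANOVA with partial eta squared, planned paired comparisons with
    Bonferroni-type correction, and default-prior (JZS) Bayes-factor
    ANOVA estimated by seeded Monte Carlo integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
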