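Package: shiftsense
Title: Sensor-Based Measurement and Multilevel Modelling of Nursing Workload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing wearable-badge and stationary-sensor records of
    hospital nursing work. Simulates badge location intervals, speech, movement
    and ambient sensor streams for intensive-care shifts with known generative
    parameters; extracts per-segment work-process features (time in zone
    classes, burstiness of speaking and of physical transitions, Shannon
    entropy of location transitions, zone-conditioned noise, temperature and
    activity means, walking time); screens features and their pairwise
    interactions with an elastic net under a strong-hierarchy two-stage scheme;
    and fits the staged two-level mixed-model sequence (intercept-only through
    cross-level interactions) predicting perceived mental and physical exertion
    on the Borg 6-20 scale, with intraclass correlation, group-mean
    reliability, level-specific pseudo-R-squared, and likelihood-ratio model
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
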