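Package: movepredict
Title: Predictability of Movement Trajectories Across Spatio-Temporal Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the predictability of individual movement
    trajectories and for studying how spatial and temporal aggregation choices
    change it. Implements stay-point detection from timestamped point
    trajectories, stay-region construction by regular-grid tessellation or
    density-based clustering, next time-bin and next place symbolic sequence
    construction, random/uncorrelated/actual entropy estimation (the latter via
    a Lempel-Ziv match-length estimator), the Fano-inequality predictability
    bound, and three estimators of actual entropy for sequences with missing
    records. A seeded synthetic mobility simulator with known ground truth and
    a sweep harness support end-to-end evaluation over spatio-temporal scales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
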