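Package: glucotrack
Title: Temporal Analysis of Neural Tracking of Blood Glucose Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how hypothalamic neuron activity tracks
    blood glucose in behaving animals: fluorescence detrending by
    triple-exponential fits through the lower convex hull, baseline
    z-normalisation, temporal-derivative and lagged cross-correlation
    analyses, hysteresis-loop construction over glucose transients, a
    chunked-bootstrap encoding model with leave-one-predictor-out
    relative contributions, single-cell classification against
    glucose-derived templates with a Bonferroni no-response rule,
    locomotion-bout detection, cross-session ROI identity matching, and
    a synthetic multichannel session generator with ground-truth labels
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
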