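Package: anchorpanel
Title: Anchored Forced-Choice Quality-Control Panels for Black-Box Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design, score, and monitor anchored two-alternative forced-choice
    (2AFC) quality-assurance panels for black-box language models. Builds
    versioned trial plans with repeat and catch blocks, parses one-line JSON
    forced-choice responses, fits an L2-regularized Bradley-Terry model with
    anchored 0-100 rescaling and parametric-bootstrap confidence intervals,
    computes repeatability, confidence-calibration, catch-trial and
    anchor-order quality-control metrics, quantifies winner reversals across
    wrapper or prompt-family conditions, and compares reruns against stored
    baseline signatures for drift review. A simulated responder with
    configurable degradation modes makes the full pipeline testable without
    querying any model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
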