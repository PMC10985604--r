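Package: obstaclegait
Title: Obstacle-Course Gait Analysis and Noninferiority Comparison of
    Virtual and Physical Walking Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse marker-based motion-capture recordings of
    children negotiating everyday walking obstacles (overstepping a bar,
    crossing a gap, balancing on a narrow beam, circumventing poles) under a
    physical and an immersive virtual-reality condition.  Implements the full
    computation chain from per-trial 3D marker trajectories to noninferiority
    verdicts: TRC trajectory input/output, kinematic gait-event detection,
    task-specific spatiotemporal parameter extraction with failure accounting,
    trial-validity screening with first-k-valid selection, per-participant
    aggregation and paired condition differencing, and z-based 95 percent
    confidence intervals compared against expert-panel noninferiority margins
    with a three-way noninferior/inconclusive/inferior decision rule.  A
    synthetic trajectory generator with closed-form ground truth stands in for
    the unavailable laboratory recordings so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
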