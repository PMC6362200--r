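Package: lcmaze
Title: Locus Coeruleus Unit Activity in a Self-Paced T-Maze Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of locus coeruleus (LC) single-unit
    activity recorded while a rat performs a self-paced T-maze
    discrimination task with rule shifts. Provides a typed session model
    (spike trains, head-LED tracking, timestamped task events, trials and
    blocks) with a plain-text on-disk bundle format; a synthetic session
    generator (constrained pseudorandom cue sequences, a criterion-driven
    rule-switching behavior agent, maze-path kinematics with
    pre-photodetector acceleration bumps, and inhomogeneous-Poisson spike
    synthesis with event-locked gains, acceleration coupling at a
    configurable lead, and reward-site suppression); kinematics primitives
    (speed, Gaussian smoothing, acceleration, binning, z-scores);
    peri-event time histograms and windowed response-ratio statistics with
    population tests; rule-shift and block-wise firing comparisons; and
    firing-acceleration coupling analyses (binned regressions, a 20 ms-step
    lag scan, and percentile-threshold onset detection with onset-triggered
    cross-correlograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
LinkingTo: Rcpp
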