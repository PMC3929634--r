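Package: skypadr
Title: Kymograph-Equivalent Segmentation and Motion Analysis of Particle Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw 2D/3D particle-tracking coordinates into the
    quantities a kymograph analysis would yield, without the manual steps:
    trajectories are partitioned by a distance-threshold scan into segments,
    each classified as moving or paused by a speed threshold, from which
    per-particle mean moving speed, percentage of time in motion, pause
    counts and durations are derived.  Also computes directional persistence
    (D/T ratio), time-averaged mean squared displacement curves, and a
    simple diffusion coefficient, with cohort-level aggregation.  Includes
    seeded generators for staged pause/move tracks, Brownian motion and
    confined oscillators so every analysis stage is testable against known
    ground truth, plus a command-line entry point for end-to-end runs on
    delimited or spreadsheet track tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
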