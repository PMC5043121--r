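Package: dodgekin
Title: Kinematic Analysis and Game Machinery for a Virtual Dodgeball
    Interception Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing full-body reaching movements recorded with
    optical motion capture during a virtual-reality ball-interception game.
    Provides marker-trajectory input/output (TRC and CSV), rigid segment-pose
    estimation from marker clusters, Euler joint-angle decomposition
    (flexion-extension, lateral bending, axial rotation), Savitzky-Golay
    smoothing and differentiation with 5%-of-peak-speed movement-onset and
    target-contact detection, whole-body centre-of-mass computation from
    anthropometric segment parameters, individualized target and impact-height
    geometry, a launch-schedule and cash-reward game engine, a ground-truth
    labelled synthetic motion generator, and an end-to-end per-trial reduction
    pipeline with condition-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
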