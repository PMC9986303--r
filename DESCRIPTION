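Package: ovigait
Title: Gait Kinematics and Neurological Scoring for Ovine Stroke Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing functional outcome in an ovine model of
    ischaemic stroke from overland walking trials captured by optical motion
    capture. Reads and writes labelled marker trajectories (a TSV dialect and
    a minimal C3D subset), conditions them with gap filling and zero-lag
    low-pass Butterworth filtering, detects stance and swing phases from hoof
    marker velocity, computes planar joint angles and global and limb-specific
    gait parameters, encodes a ten-criterion composite neurological scoring
    rubric, and implements the study statistics: intraclass correlation
    repeatability with bootstrap and parametric intervals, velocity adjustment
    by regression, pre/post linear mixed models with a random animal effect,
    Stata-convention medians and quartiles, and correlation-matrix principal
    component analysis with Kaiser-Meyer-Olkin adequacy and Bartlett
    sphericity. A deterministic synthetic quadruped-gait generator with
    injectable post-stroke deficits provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
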