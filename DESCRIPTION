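Package: vptrack
Title: Verified-Position-Corrected Dead-Reckoning of Animal Movement Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs fine-scale animal movement paths from animal-attached
    inertial sensors (tri-axial accelerometers and magnetometers, with optional
    pressure) by dead-reckoning: tilt-compensated compass headings and dynamic
    body acceleration (VeDBA) based speed estimates are integrated into
    geo-referenced pseudo-tracks, optionally advected by external current-flow
    vectors, and periodically anchored to sparse Verified Positions (e.g. GPS
    fixes) via segment-wise distance and heading correction factors. Includes
    magnetometer hard-/soft-iron calibration, asymmetric least squares pressure
    baseline estimation, speed models for terrestrial, aquatic and aerial
    locomotion, net-error and distance-moved accuracy metrics as a function of
    the Verified Position correction rate, and a closed-loop movement simulator
    (correlated random walk ground truth, consistent sensor streams, noisy
    dropout-prone fixes, current fields) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse,
    withr
Config/testthat/edition: 3
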