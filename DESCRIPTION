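Package: pursuittrack
Title: Spatial and Temporal Tracking Error for Pursuit-Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of continuous pursuit-tracking data in which a cursor,
    controlled on the vertical axis only, follows a target moving along a
    trigonometric (Wulf-Schmidt) trajectory. Generates target trajectories and
    whole counterbalanced sessions, simulates synthetic cursor pursuits with
    known lag, gain, offset and noise, detects direction changes (local extrema
    with a prominence criterion), matches cursor to target direction changes
    under similarity and proximity assumptions, estimates the intended target
    sample for every cursor sample, and computes the classical temporal
    tracking error alongside the spatial tracking error, anticipation rates,
    quality-control flags and per-segment/per-block summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
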