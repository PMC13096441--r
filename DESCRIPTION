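Package: motorpeth
Title: Perievent Analysis of Movement-Related Neural Activity Across Sleep and Wake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing extracellular spike trains recorded alongside
    synchronized video and EMG in developing sensorimotor systems. Implements
    LED-pulse validation and dummy-frame repair of video frame clocks,
    ROI pixel-change movement detection with twitch-isolation and wake-bout
    rules, rule-based sleep/wake state scoring, perievent time histograms with
    baseline z-scoring and classification of twitch- and wake-active neurons,
    temporal response metrics (peak latency, width at half-height, premovement
    proportion, Fano factor), limb-trajectory kinematics with direction
    (eta-squared) and amplitude (r-squared) selectivity, and group-level
    statistics with robust MAD outlier handling. A synthetic-session generator
    with full ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
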