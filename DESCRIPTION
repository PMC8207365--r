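Package: ethosmooth
Title: Rule-Based Smoothing and Evaluation of Nocturnal Ungulate Behavior Timelines
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning per-frame detections and classifier
    probabilities from overnight zoo-enclosure video (1 fps) into ethogram
    timelines over the states standing, lying-head-up (LHU), lying-head-down
    (LHD) and absent. Implements detection postfiltering (confidence
    threshold, one box per frame), 7-second interval aggregation, two-stream
    prediction fusion with rolling averages and absence injection, a
    configurable transition-rule postprocessor that removes implausibly short
    behavior phases, ethogram evaluation (accuracy, per-class recall /
    precision / f-score, phase counts and durations with across-night
    summaries), bounding-box IoU and AP@t detection metrics, and a
    semi-Markov night simulator with classifier-like noise so the whole
    pipeline can be exercised end-to-end without real video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
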