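Package: socialick
Title: Multi-Animal Operant Licking Sessions: Engine, Microstructure and
    Social Proximity Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pure-software toolkit for multi-animal oral operant
    self-administration experiments in which individual rats are identified
    by implanted RFID tags while sharing a chamber with two drinking spouts.
    Provides a deterministic session engine (RFID debouncing, lick-to-animal
    attribution within a detection window, fixed- and variable-ratio
    reinforcement schedules, reward and cue dispatch, syringe-pump
    calibration arithmetic), lick-microstructure analytics (cluster
    segmentation by pause threshold, interlick intervals, latency, intake),
    social-proximity analytics over camera object-detection tables (spout
    position normalization, quadrant occupancy, head-pair and head-to-spout
    distances, density maps, correlation), and a synthetic cohort simulator
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
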