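Package: droneactivity
Title: Honeybee Drone Hive-Entrance Activity from Dual-Sensor RFID Logs
Version: 0.1.0
Authors@R:
    person("droneactivity", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Reconstructs honeybee drone departure and arrival events from raw
    two-sensor (A/B) RFID reader logs via the directional crossing grammar
    (A,B,B = departure; B,A,A = arrival), builds inside/outside time spans,
    classifies them into duration-based behavior categories (exit/entry,
    orientation flight, DCA scouting, resting, departed drone), and aggregates
    per-drone, per-hour and per-day activity summaries with the associated
    nonparametric statistics (Mann-Whitney U, chi-square goodness of fit,
    Pearson weather correlations). Includes an agent-based simulator of drone
    entrance traffic that emits both the noisy read stream a dual-antenna
    reader would record and the ground-truth event log, for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
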