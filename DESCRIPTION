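Package: meaburst
Title: Burst Detection and Network-Activity Phenotyping for Multielectrode
    Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity recorded from
    neuronal cultures on multielectrode arrays (MEAs): fixed-threshold spike
    detection on raw traces, max-interval burst detection with merge and
    minimum-size rules, seven network-activity parameters (total spikes,
    percentage of spikes in bursts, burst rate, burst duration, burst-pattern
    coefficient of variation, network size, correlation index), one-way ANOVA
    with Fisher's PLSD post-hoc comparisons across culture conditions, and a
    barcode classification of knockdown phenotypes per parameter and day in
    vitro. Includes a seeded generative simulator of developing network
    activity (tonic Poisson firing plus jittered synchronized network bursts)
    with condition presets, so every pipeline stage is testable without raw
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
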