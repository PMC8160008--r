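Package: noisescape
Title: Community Noise Metrics, Sound-Source Prevalence and Monitoring-Design Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing urban community noise from minute-resolution
    A-weighted sound-level logs and coupled audio-classifier output. Computes
    equivalent continuous sound levels (LAeq) over hourly, daily, daytime and
    nighttime windows, the event-threshold Intermittency Ratio at configurable
    cutoffs, sound-source presence and prevalence (% site-time) across spatial
    and temporal strata, level-source linkage in 5-dB bins, flight-path
    proximity stratification, positive predictive value validation, stratified
    median/IQR summaries with rank-sum comparisons, empirical CDF curves, and a
    short-term versus long-term representativeness resampling analysis. Includes
    a synthetic-data generator (diurnal profiles by land-use archetype, AR(1)
    short-term noise, Poisson-arriving sound events, coupled multi-label source
    streams) emulating combined week-long rotating and year-long fixed
    monitoring designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
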