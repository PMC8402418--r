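Package: aggirhome
Title: Rule-Based Detection of Activities of Daily Living and AGGIR Scoring
    from Smart-Home Sensor Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complex-event-processing toolkit for ambient assisted living.
    Raw smart-home sensor records (time, sensor, value) are filtered into typed
    events, atomic activities are derived from device fluents, and complex
    situations (toileting, dressing, transfers, cooking, alimentation) are
    assembled under Allen interval relations with metric bounds and precedence
    constraints. Daily counts of complete situations are scored against the
    AGGIR dependency grid's per-variable criteria, yielding a two-state
    (dependent/independent) weekly verdict per variable, plus anomaly detection
    (devices left on, doors left open, irregular routines) and planned-task
    checking for medical devices such as glucometers. Includes a scripted
    smart-home simulator, reference weekly scenarios, a randomized scenario
    generator with ground-truth labels, and a small time-scoped query language
    over device value streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    vctrs,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
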