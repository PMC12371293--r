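Package: addhrvr
Title: Movement-Adjusted Heart Rate Variability Triggers for
    Just-in-Time Adaptive Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting additional (nonmetabolic) heart rate
    variability reductions (AddHRVr) from ambulatory interbeat-interval
    streams and for evaluating just-in-time adaptive interventions that
    such reductions trigger.  Covers per-minute HRV feature extraction
    (RMSSD, SDNN, spectral band power) with artifact screening,
    person-specific calibration of RMSSD against bodily movement, the
    real-time "13 out of 28" trigger rule with a 60-minute silence mode,
    offline scanning for virtual (never-emitted) triggers, construction of
    pre/during/post intervention outcome windows, multilevel
    proximal-effect models for microrandomized trials, MRT sample-size
    calculation, and a synthetic ambulatory-data generator that makes the
    whole chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
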