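Package: cvue
Title: Coefficient of Variation of the EEG Upper Envelope for Objective Pain Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies the presence of pain from resting-state EEG by the
    coefficient of variation of the upper envelope (CVUE) of band-limited
    brain oscillations. Implements the full pipeline from raw multichannel
    recordings (CSV or EDF) to per-epoch CVUE traces in the alpha, beta and
    gamma bands: DC-offset removal, interquartile-range artifact filtering
    with linear-interpolation replacement, 5th-order Butterworth band
    decomposition, min-max and unity normalization, per-epoch Hilbert
    analytic-signal envelopes, and the CVUE statistic on 1-s windows with
    50% overlap. Group-level inference uses exact or Monte-Carlo permutation
    tests and Spearman correlation; a binary pain call thresholds beta-band
    CVUE at electrode FC5. A synthetic EEG cohort generator with controlled
    envelope modulation, eye-blink and EMG artifact injection provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
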