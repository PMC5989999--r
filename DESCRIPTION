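Package: eegdyn
Title: Dynamic Network-State Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the temporal dynamics of network states in
    multichannel scalp EEG. Sliding-window analysis of band-filtered
    10-second segments yields window-to-window correlation dynamics
    matrices (CDM, built from channel-to-channel correlation patterns)
    and power dynamics matrices (PDM, built from per-channel band-power
    distributions). Each matrix is summarized by its mean, its contrast
    and its Brenner sharpness, giving 36 dynamics measures per segment
    across six frequency bands. Nonstationarity of the measures is
    tested against amplitude- and cross-correlation-adjusted (IAAFT)
    surrogate time series, and segments are clustered into
    electroclinical groups via purity-optimized thresholds and k-means.
    Includes a synthetic EEG generator (normal infant background,
    burst suppression, hypsarrhythmia, stationary controls) and EDF
    input/output so the whole pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
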