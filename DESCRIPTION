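Package: drowsyfuse
Title: Multi-Sensor Driver Fatigue Recognition from EEG, ECG and Behaviour Labels
Version: 0.1.0
Authors@R: person("drowsyfuse", "maintainers", email = "maintainers@drowsyfuse.dev",
                  role = c("aut", "cre"))
Description: Toolkit for physiological driver-fatigue recognition. Provides
    synthetic EEG/ECG/label-stream/image generators, signal I/O and epoching,
    zero-phase Butterworth preprocessing (band-pass, powerline notch, detrend),
    EEG band-power and entropy features (sample, approximate, fuzzy and
    spectral entropy), matched-filter R-peak detection with time-domain heart
    rate variability statistics, gradient-boosted tree / SVM / logistic
    classifier harnesses, a small convolutional image classifier for distracted
    driving, and a real-time sliding-window mode-fusion feedback engine that
    maps fused label patterns to fatigue severity levels with a persistence
    threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
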