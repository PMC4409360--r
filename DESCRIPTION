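Package: spikeosc
Title: Detection and Quantification of Oscillations in Single-Unit Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying oscillatory modulation in
    single-unit spike trains modelled as inhomogeneous Poisson processes.
    Provides a spike-train simulator (cosine-modulated rate functions with
    optional absolute refractory period and frequency jitter), Welch power
    spectra of binned spike trains with a signal-to-noise-ratio statistic
    measured against a high-frequency noise band, closed-form spectra of
    finite oscillatory Poisson processes, a firing-rate-unbiased oscillation
    "modulation index" estimator with corrections for Welch windowing and for
    refractory-period distortion, Monte-Carlo significance thresholds, and an
    analytic planner for the recording duration required to detect an
    oscillation at a target SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
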