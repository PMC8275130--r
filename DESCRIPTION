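Package: habpipe
Title: Spectral, Time-Frequency and Coherence Analysis of Deep-Brain LFP
    and Cortical Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for analysing local field potentials
    recorded from deep-brain electrodes together with cortical sensor-array
    (MEG-like) signals during event-related paradigms. Provides bipolar
    re-referencing, zero-phase filtering and epoching; parameterization of
    power spectra into an aperiodic 1/f-like component plus Gaussian
    oscillatory peaks; Morlet wavelet time-frequency decomposition with
    baseline percent-change normalization; cross-trial time-resolved
    coherence; nonparametric cluster-based permutation statistics with
    exhaustive small-sample enumeration; a frequency-domain (DICS-style)
    beamformer on regular source grids; and random-intercept mixed-effects
    models relating band-limited power and coherence to stimulus valence
    and arousal ratings. A calibrated synthetic-data generator emulating
    a three-condition emotional picture-viewing study makes every stage
    testable without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
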