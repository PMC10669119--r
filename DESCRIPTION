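Package: puffstat
Title: Time, Frequency and Stationarity Analysis of MRI Gradient-Switching Artifact Puffs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the voltage bursts ("artefact puffs")
    that magnetic-field-gradient switching induces on electrophysiological
    recordings made during MRI. Provides a synthetic generator of
    pseudo-periodic, amplitude-modulated puff trains with ground-truth
    boundaries; envelope-based puff segmentation and Z-score normalization;
    time-domain (RMS, mean puff, normalized mean-square error) and
    frequency-domain (Welch-WOSA power spectral density, spectral moments)
    features; the KPSS level/trend stationarity test with Monte-Carlo
    critical values; and a surrogate-based time-frequency stationarity test
    built on a multitaper Hermite spectrogram, phase-randomization
    surrogates, local-versus-global spectral divergences, a gamma-fitted
    null threshold and the index of non-stationarity (INS). A study driver
    runs the global (whole recording) and local (per puff) analyses over
    sequence-by-orientation variants and emits report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    fitdistrplus,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
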