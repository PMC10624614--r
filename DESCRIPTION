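Package: slowwave
Title: Wavelet Semblance and Coherence Reactivity Indices for Cerebral
    Slow-Wave Oscillations
Version: 0.1.0
Authors@R:
    person("Neuro", "Optics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying cerebrovascular and cerebral metabolic
    reactivity from multichannel optical and systemic neuromonitoring time
    series (broadband near-infrared spectroscopy, diffuse correlation
    spectroscopy, arterial blood pressure). Implements a continuous Morlet
    wavelet engine with cross-wavelet semblance (instantaneous phase
    alignment, -1 to +1) and smoothed wavelet coherence (spectral
    similarity, 0 to 1) over the slow-wave band (0.003-0.05 Hz), the
    surrounding preprocessing chain (threshold and moving-SD artifact
    removal, spline repair, discrete wavelet denoising, resampling and
    synchronization), per-subject band-mean reactivity indices for named
    signal pairs, small-cohort outcome statistics (log10 transforms,
    D'Agostino-Pearson normality, ordinary least squares regression,
    one-way ANOVA, Welch-corrected two-group tests, threshold-based
    outcome classification), and a synthetic-cohort generator with known
    slow-wave coupling structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
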