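Package: betadyn
Title: Beta-Band Oscillation Dynamics, Burst Detection and Path Models for
    Cortico-Subthalamic Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal analysis of beta-band (13-30 Hz) activity in paired
    motor-cortex ECoG and subthalamic local field potential recordings.
    Provides Hanning-windowed periodogram power spectra with band
    normalization, imaginary coherence connectivity, Morlet-wavelet beta-burst
    detection (amplitude, rate, long-burst probability), behavioural and
    tracer-binding indices, normality-gated group statistics, and
    maximum-likelihood observed-variable path models with fit indices,
    a correlated-endpoint Bonferroni adjustment, a cumulative-sum composite
    neurodegeneration score and behaviour-versus-degeneration curves. A
    synthetic cohort generator with known ground truth (1/f background,
    injected bursts, lagged inter-regional coupling, linear-Gaussian
    endpoints) makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
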