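Package: snapflim
Title: Single-Snapshot Rapid Lifetime Determination for Time-Gated SPAD
    Fluorescence Lifetime Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling, sensor simulation and estimation tools for
    rapid lifetime determination (RLD) with dual-gate time-gated
    single-photon avalanche diode (SPAD) array cameras. Implements a
    closed-form and numerical model of periodic pulsed-excitation
    mono-exponential fluorescence decay with instrument response and boxcar
    gating; a binary-frame sensor simulator producing correlated gated (G2)
    and full-period (INT) count images with dark counts, hot pixels,
    gate-edge jitter and saturation; lookup-table inversion of the G2/INT
    count ratio to per-pixel lifetime maps; a re-convolution nonlinear
    least-squares reference fitter for gate-scanned decays; and
    lifetime-dynamics analysis (baseline-relative lifetime-change maps,
    wavefront localization and propagation-speed estimation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
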