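# snapflim

Single-snapshot rapid lifetime determination (RLD) for dual-gate,
time-gated SPAD-array fluorescence lifetime imaging (FLIM).

## The problem

Fluorescence lifetime imaging derives contrast from the nanosecond decay
time τ of fluorescence emission rather than its intensity, which makes it
robust to dye concentration, excitation non-uniformity and photobleaching.
Classical time-domain FLIM scans a narrow detection gate across the laser
period and fits the assembled decay — accurate, but two orders of magnitude
too slow for video-rate imaging of dynamic events such as intracellular
calcium waves.

Dual-gate SPAD array cameras change the arithmetic. In every binary frame
each pixel records two correlated one-bit outcomes over N laser pulses: a
**G2** bit (a photon detected inside a gate `[s, s + W]` of each period) and
an **INT** bit (a photon detected anywhere in the period `T`). Per frame the
joint outcome is (0,0), (1,0) or (1,1) — never (0,1) — and F one-bit frames
are accumulated on-chip into a pair of count images (F = 4096 in 12-bit
mode, F = 4 × 255 = 1020 in 10-bit mode).

For a mono-exponential decay `A0 · exp(-t/τ)` under a pulse train of period
T, the accumulated gated and full-period signals have closed forms, and
their ratio depends on τ but not on the amplitude:

    R_{T,W}(s) = ( e^{-s/τ} − e^{-(s+W)/τ} ) / ( 1 − e^{-T/τ} )

which for s = 0 reduces to `R = (1 − e^{-W/τ}) / (1 − e^{-T/τ})`. R is
strictly monotone in τ for the practical gate placements, so a precomputed
lookup table inverts one measured `G2/INT` ratio to a per-pixel lifetime —
a full lifetime map from a *single snapshot*, at roughly 1/100th of the
acquisition time of a 100-delay gate scan.

`snapflim` implements the full desk-scale workflow around this estimator:

- **decay model** — periodic mono-exponential decay, IRF re-convolution
  (cyclic convolution over one period), boxcar gating and gated integrals,
  with the closed forms above (`periodic_mono_exp()`, `recorded_signal()`,
  `gate_ratio()`, `analytic_gate_pair()`);
- **sensor simulator** — the exact nested-binomial dual-gate frame model
  with detection efficiency, dark-count maps with hot pixels, gate-edge
  jitter and pile-up saturation (`simulate_pair()`,
  `simulate_decay_scan()`, `make_dcr_map()`);
- **RLD estimator** — lookup-table construction and inversion, dark and
  saturation correction, lifetime maps with validity masks, shot-noise
  precision studies (`build_lut()`, `invert_ratio()`, `estimate_map()`,
  `precision_study()`);
- **NLSF reference** — re-convolution nonlinear least-squares fitting of
  gate-scanned decays, IRF estimation, paired estimator comparison
  (`nlsf_fit()`, `estimate_irf()`, `compare_estimators()`);
- **dynamics** — baseline-relative Δτ/τ maps, ROI profiles, sub-pixel
  halfway-point wavefront localization and propagation-speed fitting, plus
  a synthetic calcium-wave generator (`delta_tau_map()`,
  `track_wavefront()`, `synth_calcium_wave()`);
- **I/O and CLI** — multi-page TIFF + JSON-sidecar interchange and a
  command-line wrapper (`write_pair()`, `read_pair()`, `cli_main()`,
  `inst/cli/snapflim`).

## Worked example

Two solvent environments of the same dye — lifetimes 1 ns and 1.65 ns —
imaged in one 12-bit snapshot with the macroscopic gate settings
(W = 3 ns, gate delay s = 5.5 ns, T = 12.5 ns at 80 MHz):

```r
library(snapflim)

gate   <- gate_window(s = 5.5, W = 3, T = 12.5)
lut    <- build_lut(gate)                      # 4096-point tau -> R table
config <- sensor_config(shape = c(64, 64), bit_depth = 12)

A0   <- matrix(2.5e-3, 64, 64)                 # uniform brightness
tau  <- cbind(matrix(1, 64, 32), matrix(1.65, 64, 32))
pair <- simulate_pair(scene_map(A0, tau), gate, config, seed = 7)
pair
#> <count_image_pair> 64 x 64 px, F = 4096; mean INT 1845.8, mean G2 49.7

map <- estimate_map(pair, lut, config = config, correct = TRUE)
map
#> <lifetime_map> 64 x 64 px, 4096 valid (100.0%), mean tau 1.321 ns

mean(map$tau[, 1:32]);  sd(map$tau[, 1:32])    # left half (1 ns)
#> 0.992 +/- 0.072 ns
mean(map$tau[, 33:64]); sd(map$tau[, 33:64])   # right half (1.65 ns)
#> 1.649 +/- 0.058 ns
```

The intensity images alone cannot distinguish the halves (equal A0); the
ratio-inverted lifetime map separates them by more than 8 pooled standard
deviations. Wavefront tracking on a synthetic calcium transient:

```r
video <- synth_calcium_wave(shape = c(20, 100), n_frames = 24, fps = 6.25,
                            pixel_size = 0.25, speed = 7.47,
                            front_width = 0.5)
track_wavefront(video, roi = c(10, 1, 100, 16), n_pre_frames = 3)
#> <wavefront_track> 18 detections, speed 7.467 +/- 0.001 um/s
```

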