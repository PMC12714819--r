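---
title: "Single-snapshot RLD for dual-gate SPAD FLIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-snapshot RLD for dual-gate SPAD FLIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapflim)
```

## The physical model

A pulsed laser with repetition period $T$ (all times in nanoseconds;
$T = 1000/f_{\mathrm{MHz}}$, so 12.5 ns at 80 MHz) excites a fluorophore
whose emission probability decays mono-exponentially,
$F_0(t) = e^{-t/\tau}/\tau$. At steady state the $T$-periodic emission is
the wrapped sum of the responses to all preceding pulses; for a
mono-exponential decay this geometric series has the closed form

$$F_{0,T}(t) = \frac{e^{-t/\tau}}{\tau\,(1 - e^{-T/\tau})},
  \qquad t \in [0, T),$$

implemented in `periodic_mono_exp()` both in closed form and as an
explicit series (terms added until one falls below $10^{-15}$ of the
running sum; the two agree to $10^{-10}$ relative and the series is kept
as an internal cross-check). A finite-width excitation pulse $x_0(t)$ and
the detector's single-photon timing response $E(t)$ enter as cyclic
convolutions over one period (`emission_from_pulse()`,
`recorded_signal()`); both kernels are stored as unit-area `[0, T)`
samples, which is valid because they are short relative to $T$.
Convolution is computed by FFT on the uniform grid, preserves the period
integral to $10^{-9}$ relative, and is associative in grouping to the same
tolerance.

## Gating and the accumulated-signal ratio

The detection gate is an ideal boxcar open on the closed interval
$[s, s+W]$ with $s \ge 0$ and $s + W \le T$ (`gate_window()`); the
full-period INT gate is $s = 0, W = T$. The accumulated signal is the
integral of the gated signal over one period (`gated_integral()`). For a
delta-excitation single-pulse decay the gated integrals have closed forms,

$$S^{(G2)} = A_0 \tau \left(e^{-s/\tau} - e^{-(s+W)/\tau}\right), \qquad
  S^{(INT)} = A_0 \tau \left(1 - e^{-T/\tau}\right),$$

and their ratio $R_{T,W}(s)$ is independent of the amplitude $A_0$. The
closed forms idealize the excitation as instantaneous and neglect the
previous-pulse carry-over inside the gate; the numerical quadrature path
quantifies the discrepancy for finite IRFs, and the two routes agree to
better than $10^{-5}$ relative at 1 ps sampling for the delta-IRF case.
The gate integral is evaluated as the exact integral of the piecewise
linear interpolant of the samples, so a constant signal gives exactly
$cW$; past the last sample the signal is linearly extrapolated to $t = T$,
which handles the jump a truncated decay has at the period wrap.

Monotonicity of $R(\tau)$ depends on gate placement: the $s = 0$ gate is
strictly decreasing in $\tau$ (from 1 towards $W/T$), a late gate past the
pulse is increasing (from 0 towards $W/T$) over practical ranges, and a
slightly offset gate rises and then falls, so `build_lut()` validates
strict monotonicity over the configured range and reports the first
reversal if there is one rather than silently producing a multivalued
inverse.

## The sensor model

Every one-bit frame integrates $N$ laser pulses. With expected detected
photons per pulse $\lambda_g$ (inside the gate) and $\lambda_t$ (whole
period), the probability that the frame bit is set is
$p = 1 - e^{-N\lambda}$ — photon arrivals are Poisson and one detection
saturates the bit. The per-pixel rates include the photon detection
efficiency and a uniform-in-time dark contribution
($\mathrm{DCR} \cdot t_{\mathrm{exp}}$ per frame, a fraction $W/T$ of it
inside the gate).

The two bits of a frame are perfectly correlated: a gated detection also
sets the INT bit, so the joint outcome is never (0,1). Accumulated over
$F$ frames this is sampled exactly by the nested-binomial factorization

$$G2 \sim \mathrm{Bin}(F, p_g), \qquad
  INT = G2 + \mathrm{Bin}\!\left(F - G2,\;
  \frac{p_t - p_g}{1 - p_g}\right),$$

which reproduces the hardware contract $0 \le G2 \le INT \le F$ without
per-pulse simulation. Pile-up saturation emerges from this model: as
$p_t \to 1$ the INT counts compress towards $F$ and their variance
collapses below Poisson. The bit-depth presets follow the hardware:
12-bit accumulates $F = 4096$ frames, 10-bit $F = 4 \times 255 = 1020$
(the small difference from $2^{10}-1$ is hardware-faithful and kept),
8-bit 255.

Gate-edge timing jitter is modelled as Gaussian edge displacements with
$\sigma = \mathrm{FWHM}/2.3548$ (defaults 109 ps rising, 153 ps falling).
Because the uncertainty is stochastic per gate signal, the default
`per_frame` mode redraws the edges for every one-bit frame (edges are
global across the array, as in hardware); a `static` per-acquisition mode
is provided. Not modelled: afterpulsing, crosstalk, rolling-readout
timing, microlens optics, and the non-instantaneous gate edge shape
beyond the jitter model. The scan trigger period $T$ is treated as the
gate-trigger period; when hardware derives the gate clock from a divided
laser clock the user must supply the effective period.

## The estimator

`estimate_map()` runs the single-snapshot pipeline: optional dark and
saturation correction, ratio $R = G2/INT$, lookup-table inversion.

* **Correction order.** Expected dark counts are subtracted first
  ($\mathrm{DCR} \cdot F t_{\mathrm{exp}}$, scaled by $W/T$ for G2), then
  the binomial compression is inverted with
  $\hat\lambda = -F\ln(1 - k/F)$, counts clipped to $F - 1$. For
  $k \ll F$ the correction changes counts by under 1%.
* **Lookup table.** 4096 log-spaced lifetimes over 0.1–10 ns by default;
  log spacing equalizes relative interpolation error. Inversion is
  monotone piecewise-linear interpolation; round-trip error is below 0.1%
  over 0.25–5 ns.
* **Masking, not clamping.** Ratios outside the table range produce `NA`
  pixels and a masked-pixel count; clamping would manufacture fake
  lifetimes at the range edges. Pixels with fewer than `min_counts` raw
  INT counts (default 10) are masked: below ~10 photons the ratio is
  dominated by counting noise and the estimate is biased.
* **Per-pixel offsets.** An optional offset map shifts the effective gate
  delay per pixel (one shifted-gate table per distinct offset), emulating
  a time-of-flight calibration; default off — the plain estimator applies
  no such correction.

Because $R$ is a ratio, the estimate is invariant to any common scaling
of the two channels, which is what makes the method robust to
concentration and illumination variations. Precision is shot-noise
limited: `precision_study()` verifies that the standard deviation of
$\hat\tau$ scales as $1/\sqrt{\mathrm{counts}}$ (log–log slope $-1/2$)
when the per-frame bit probability stays well below 1. For photon budgets
up to $10^4$ this requires $F$ larger than the hardware presets
($F = 65536$ is used in the precision and comparison studies); with
$F = 1020$ and such budgets, pile-up rather than shot noise would
dominate, which is a property of the sensor, not of the estimator.

## The NLSF reference

The reference estimator assembles a full gate-scanned decay (one
acquisition per delay, stepped in multiples of the 17.6 ps gate
resolution) and fits
$\mathrm{counts}(s) = b + a \int_{s}^{s+W} (I \circledast F_{0,T})(t - t_0)\,dt$
by Levenberg–Marquardt least squares (`minpack.lm::nls.lm`). Each scan
point is modelled as the integral over the full gate width — the detector
integrates a 3 ns gate, and point-sampling the model would bias $\tau$.
Fits are unweighted by default with optional Poisson-variance weights
(the choice is exposed because reference implementations differ);
lifetimes are bounded to 0.05–20 ns; three starts (0.5×, 1×, 2× a
moment-based guess) are tried, the best residual wins and ties go to the
smaller lifetime. Non-convergence is reported in the result, never
thrown. On noiseless synthetic scans the fitted $\tau$ matches the truth
to 0.1% and agrees with the RLD estimate to well under 2%; a free time
offset absorbs pixel-wise time-of-flight shifts when an IRF is supplied.
The IRF itself can be estimated from a zero-lifetime scan: with a gate
much wider than the pulse, the scan counts trace the pulse's survival
function and the IRF is its negative derivative (`estimate_irf()`).

`compare_estimators()` accounts for acquisition time: a 100-delay scan
costs 100× the time of one snapshot at the same per-acquisition photon
budget, which is the core trade the single-snapshot method exploits.

## Lifetime dynamics

Dynamic events are visualized as the baseline-relative change
$\Delta\tau/\tau = (\tau_{\mathrm{current}} - \tau_{\mathrm{baseline}})/
\tau_{\mathrm{baseline}}$ against a pre-activation baseline (mask-aware
mean over the leading frames). A wavefront is localized on a 1-D ROI
profile (mask-aware mean across the ROI width) as the first crossing of
half the plateau, linearly interpolated between the bracketing samples.
Design choices where the procedure is genuinely open:

* **Plateau estimator.** Median of the top decile of profile values — a
  robust maximum that single-pixel outliers cannot move. Ties/multiple
  crossings: the first crossing along the propagation axis wins.
* **Noise floor.** A front is only accepted if the plateau exceeds 3× the
  pre-activation profile standard deviation, preventing spurious
  detections before wave onset.
* **Plateau development gate.** While the front is still entering the
  ROI, fewer samples than the top decile sit on the plateau, the plateau
  estimate is biased low and the halfway threshold with it; fitting those
  early detections would bend the position–time line. `track_wavefront()`
  therefore uses only frames whose plateau reaches 90% of its maximum
  over the video (`plateau_gate = 0.9`). With the gate in place the
  noise-free pipeline recovers a seeded speed to better than 1%, and to
  ~5% with per-pixel lifetime noise of 2% of baseline.
* **Interpolation.** Linear between the bracketing samples; near the
  sigmoid midpoint the profile is locally linear, so the sub-pixel error
  is far below a quarter pixel.

The synthetic generator `synth_calcium_wave()` emulates the
phenomenology of an intracellular calcium transient: a sigmoidal
lifetime-increase front of fractional amplitude 0.15 (a typical
calcium-release lifetime change) sweeping at constant speed (default
7.47 µm/s at 6.25 fps, the regime of fast intracellular calcium waves),
with optional Gaussian estimation noise. It does **not** emulate cell
geometry, intensity-dependent estimator noise, photobleaching, or fronts
with curvature or varying speed — so the end-to-end tests demonstrate
correctness of the tracking arithmetic, not performance on real
morphology.

## Numerical choices and problem sizes

* Default grid spacing is 4.4 ps (a quarter of the 17.6 ps hardware gate
  step); quadrature oracles use 1 ps.
* Gate masks use the closed interval $s \le t \le s+W$; the gate integral
  uses interpolant-exact trapezoid weights so the boxcar area equals $W$.
* All randomness flows through explicit seeds; `simulate_pair()` and the
  study functions are bitwise-reproducible under a fixed seed. No global
  RNG state is consumed implicitly.
* Test and acceptance problem sizes are chosen to keep the default suite
  in seconds on one CPU: 64×64 or smaller arrays for snapshot studies,
  $10^3$ repeats per photon budget in the precision study, 100-delay
  scans with 20–25 NLSF fits in the comparison, 24-frame 20×100 videos
  for tracking. Each of these is stated where used and can be scaled up
  by the caller.

## Known limitations

The inversion assumes a mono-exponential decay; multi-exponential
mixtures yield an intensity-weighted apparent lifetime with
gate-dependent bias, and no unmixing is attempted. The closed forms
assume a delta IRF — for late gates (several IRF widths past the pulse)
this is accurate, but gates overlapping the excitation require either
the numerical forward model or an IRF-aware table. Dark and pile-up
corrections use the uniform-dark and binomial models above; afterpulsing
and crosstalk are outside the model. Out-of-range ratios are masked, so
heavily saturated or photon-starved pixels return no estimate rather
than a wrong one.
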