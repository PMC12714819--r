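#' Mono-exponential fluorescence decay parameters
#'
#' @param tau Fluorescence lifetime in ns; must be > 0.
#' @param A0 Signal amplitude: expected detected-photon scale per excitation
#'   pulse (dimensionless, >= 0).
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(tau, A0 = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("lifetime `tau` must be a single positive number (ns)",
         call. = FALSE)
  }
  if (!is.numeric(A0) || length(A0) != 1L || !is.finite(A0) || A0 < 0) {
    stop("amplitude `A0` must be a single non-negative number", call. = FALSE)
  }
  structure(list(tau = tau, A0 = A0), class = "decay_params")
}

#' Single-pulse mono-exponential decay
#'
#' The probability density of photon emission at time t after an
#' instantaneous excitation: `exp(-t/tau)/tau`, sampled on one period.
#'
#' @param grid A [time_grid()].
#' @param params A [decay_params()].
#' @return A `periodic_signal` (label `"decay"`); strictly decreasing with
#'   value `1/tau` at t = 0. Note this is the single-pulse response truncated
#'   to `[0, T)`, not the periodic steady state (see [periodic_mono_exp()]).
#' @examples
#' g <- time_grid(12.5, dt = 0.01)
#' d <- mono_exp_decay(g, decay_params(tau = 1))
#' d$values[1]  # 1/tau = 1
#' @export
mono_exp_decay <- function(grid, params) {
  stopifnot(is_time_grid(grid), inherits(params, "decay_params"))
  periodic_signal(exp(-grid$t / params$tau) / params$tau, grid, "decay")
}

#' Steady-state T-periodic mono-exponential decay
#'
#' Under a pulse train of period T the emission at steady state is the
#' wrapped sum of single-pulse decays from all preceding pulses. For a
#' mono-exponential decay this geometric series has the closed form
#' `exp(-t/tau) / (tau * (1 - exp(-T/tau)))` on `[0, T)`.
#'
#' @inheritParams mono_exp_decay
#' @param method `"closed"` (default) uses the geometric-series closed form;
#'   `"series"` sums shifted single-pulse decays, stopping once a term falls
#'   below `1e-15` of the running sum (used as an internal cross-check).
#' @return A `periodic_signal` (label `"decay"`) with period integral 1.
#' @export
periodic_mono_exp <- function(grid, params, method = c("closed", "series")) {
  stopifnot(is_time_grid(grid), inherits(params, "decay_params"))
  method <- match.arg(method)
  tau <- params$tau
  v <- switch(method,
    closed = exp(-grid$t / tau) / (tau * (1 - exp(-grid$T / tau))),
    series = {
      acc <- exp(-grid$t / tau) / tau
      k <- 1L
      repeat {
        term <- exp(-(grid$t + k * grid$T) / tau) / tau
        acc <- acc + term
        if (max(term) < 1e-15 * max(acc) || k > 100000L) break
        k <- k + 1L
      }
      acc
    }
  )
  periodic_signal(v, grid, "decay")
}

# Cyclic (circular) convolution of two sampled signals over one period,
# approximating the continuous convolution integral: result_i = dt * sum_j
# a_j b_{(i-j) mod n}. FFT-based, O(n log n).
cyclic_convolve <- function(a, b, dt) {
  n <- length(a)
  stopifnot(length(b) == n)
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / n * dt
}

#' Emission under a finite-width excitation pulse
#'
#' Cyclic convolution of the (unit-area, T-periodic) excitation pulse with
#' the periodic decay: the steady-state emitted signal for a non-instantaneous
#' pulse. The convolution preserves the period integral.
#'
#' @param pulse A `periodic_signal` pulse profile (see [pulse_profile()]).
#' @param decay A `periodic_signal` decay on the same grid.
#' @return A `periodic_signal` (label `"decay"`) on the shared grid.
#' @export
emission_from_pulse <- function(pulse, decay) {
  stopifnot(inherits(pulse, "periodic_signal"),
            inherits(decay, "periodic_signal"))
  if (!same_grid(pulse$grid, decay$grid)) {
    stop("pulse and decay are sampled on different time grids", call. = FALSE)
  }
  v <- cyclic_convolve(pulse$values, decay$values, pulse$grid$dt)
  periodic_signal(v, decay$grid, "decay")
}

#' Recorded signal: IRF re-convolved periodic decay
#'
#' The signal a time-gated detector records at steady state: the cyclic
#' convolution of the global instrument response (detector response convolved
#' with the excitation pulse) with the periodic mono-exponential decay,
#' scaled by the amplitude `A0`. Convolution is associative, so the grouping
#' `(E * x0) %convolve% F` equals `E * (x0 %convolve% F)`.
#'
#' @param pulse Excitation [pulse_profile()].
#' @param det [detector_response()] on the same grid.
#' @param params [decay_params()] (amplitude `A0` scales the output).
#' @param grid The shared [time_grid()].
#' @return A `periodic_signal` with label `"recorded"`.
#' @export
recorded_signal <- function(pulse, det, params, grid) {
  stopifnot(is_time_grid(grid), inherits(params, "decay_params"))
  if (!same_grid(pulse$grid, grid) || !same_grid(det$grid, grid)) {
    stop("pulse, detector response and grid must share the same sampling",
         call. = FALSE)
  }
  decay <- periodic_mono_exp(grid, decay_params(params$tau, A0 = 1))
  irf <- cyclic_convolve(det$values, pulse$values, grid$dt)
  v <- params$A0 * cyclic_convolve(irf, decay$values, grid$dt)
  periodic_signal(v, grid, "recorded")
}
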