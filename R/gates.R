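#' Boxcar gate window
#'
#' The (s, W, T) gate definition shared by the forward model, the sensor
#' simulator and the estimators: an ideal square gate open on `[s, s + W]`
#' within each laser period of length T. The full-period (INT) gate is
#' `gate_window(0, T, T)`.
#'
#' @param s Gate offset relative to the excitation trigger, ns (>= 0).
#' @param W Gate width, ns (> 0).
#' @param T Laser period, ns; requires `s + W <= T`.
#' @return An object of class `gate_window`.
#' @examples
#' g2 <- gate_window(s = 5.5, W = 3, T = 12.5)
#' int <- gate_window(s = 0, W = 12.5, T = 12.5)
#' @export
gate_window <- function(s, W, T) {
  stopifnot(is.numeric(s), is.numeric(W), is.numeric(T),
            length(s) == 1L, length(W) == 1L, length(T) == 1L)
  if (!is.finite(s) || s < 0) {
    stop("gate offset `s` must be >= 0 ns", call. = FALSE)
  }
  if (!is.finite(W) || W <= 0) {
    stop("gate width `W` must be > 0 ns", call. = FALSE)
  }
  if (!is.finite(T) || T <= 0) stop("period `T` must be > 0 ns", call. = FALSE)
  if (s + W > T + 1e-9) {
    stop(sprintf("gate must close within the period: s + W = %g > T = %g",
                 s + W, T), call. = FALSE)
  }
  structure(list(s = s, W = W, T = T), class = "gate_window")
}

#' @export
print.gate_window <- function(x, ...) {
  cat(sprintf("<gate_window> [%g, %g] ns in a %g ns period (W = %g ns)\n",
              x$s, x$s + x$W, x$T, x$W))
  invisible(x)
}

is_full_period <- function(gate) {
  abs(gate$s) < 1e-12 && abs(gate$W - gate$T) < 1e-9
}

same_gate <- function(a, b, tol = 1e-9) {
  abs(a$s - b$s) < tol && abs(a$W - b$W) < tol && abs(a$T - b$T) < tol
}

#' Sampled gate indicator
#'
#' Indicator of the closed interval `[s, s + W]` on the grid: 1 where
#' `s <= t <= s + W`, 0 elsewhere. The full-period gate is all ones.
#'
#' @param gate A [gate_window()].
#' @param grid A [time_grid()] with the same period.
#' @return A `periodic_signal` of 0/1 samples (label `"gate"`).
#' @export
gate_mask <- function(gate, grid) {
  stopifnot(inherits(gate, "gate_window"), is_time_grid(grid))
  if (abs(gate$T - grid$T) > 1e-9) {
    stop("gate period and grid period differ", call. = FALSE)
  }
  eps <- grid$dt * 1e-6
  v <- as.numeric(grid$t >= gate$s - eps & grid$t <= gate$s + gate$W + eps)
  periodic_signal(v, grid, "gate")
}

#' Gated integral of a periodic signal
#'
#' The accumulated signal in a boxcar gate: the integral of the signal over
#' `[s, s + W]` in one period. Computed as the exact integral of the linear
#' interpolant of the samples, so a constant signal c gives exactly `c * W`
#' and the quadrature error is O(dt^2) for smooth signals. Beyond the last
#' sample (t in `(T - dt, T]`) the signal is linearly extrapolated, which
#' handles the jump a truncated decay has at the period wrap.
#'
#' @param signal A `periodic_signal`.
#' @param gate A [gate_window()] with the same period.
#' @return The scalar integral (signal units x ns).
#' @export
gated_integral <- function(signal, gate) {
  stopifnot(inherits(signal, "periodic_signal"),
            inherits(gate, "gate_window"))
  grid <- signal$grid
  if (abs(gate$T - grid$T) > 1e-9) {
    stop("gate period and signal period differ", call. = FALSE)
  }
  t <- grid$t
  v <- signal$values
  n <- length(v)
  # extend the sample set to t = T by linear extrapolation of the last pair
  t_ext <- c(t, grid$T)
  v_ext <- c(v, if (n >= 2) 2 * v[n] - v[n - 1] else v[n])
  a <- gate$s
  b <- min(gate$s + gate$W, grid$T)
  trapz_interp(t_ext, v_ext, a, b)
}

# Integral over [a, b] of the piecewise-linear interpolant through (t, v).
# t must be sorted increasing and cover [a, b].
trapz_interp <- function(t, v, a, b) {
  if (b <= a) return(0)
  f <- stats::approxfun(t, v, rule = 2)
  idx <- which(t > a & t < b)
  knots <- c(a, t[idx], b)
  vals <- c(f(a), v[idx], f(b))
  sum(diff(knots) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Closed-form accumulated gate signals for a delta-excitation decay
#'
#' For an ideal (delta) instrument response and a single-pulse
#' mono-exponential decay `A0 * exp(-t/tau)`, the accumulated G2 and INT
#' signals have closed forms:
#' \deqn{S^{G2} = A_0 \tau (e^{-s/\tau} - e^{-(s+W)/\tau})}
#' \deqn{S^{INT} = A_0 \tau (1 - e^{-T/\tau})}
#'
#' @param params [decay_params()].
#' @param gate [gate_window()].
#' @return Named list with `g2` and `int_` (both >= 0, `g2 <= int_`).
#' @examples
#' analytic_gate_pair(decay_params(tau = 1), gate_window(5.5, 3, 12.5))
#' @export
analytic_gate_pair <- function(params, gate) {
  stopifnot(inherits(params, "decay_params"), inherits(gate, "gate_window"))
  tau <- params$tau
  g2 <- params$A0 * tau * (exp(-gate$s / tau) - exp(-(gate$s + gate$W) / tau))
  int_ <- params$A0 * tau * (1 - exp(-gate$T / tau))
  list(g2 = g2, int_ = int_)
}

#' Expected G2/INT accumulated-signal ratio
#'
#' The ratio of the gated (G2) to full-period (INT) accumulated signals for a
#' mono-exponential decay — the quantity the single-snapshot RLD estimator
#' inverts. Independent of the amplitude `A0`:
#' \deqn{R_{T,W}(s) = \frac{e^{-s/\tau} - e^{-(s+W)/\tau}}{1 - e^{-T/\tau}}}
#' which for `s = 0` reduces to
#' `(1 - exp(-W/tau)) / (1 - exp(-T/tau))`.
#'
#' R is strictly decreasing in tau for an `s = 0` gate with `W < T`, and
#' strictly increasing over practical lifetime ranges for a late gate
#' (`s > 0` past the pulse). Its large-tau limit is `W/T`.
#'
#' @param tau Lifetime(s) in ns, vectorized; all > 0.
#' @param gate [gate_window()].
#' @return Ratio(s) in (0, 1].
#' @examples
#' gate_ratio(1, gate_window(0, 3, 12.5))     # ~0.95022
#' gate_ratio(1.65, gate_window(5.5, 3, 12.5)) # ~0.02990
#' @export
gate_ratio <- function(tau, gate) {
  stopifnot(inherits(gate, "gate_window"))
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("lifetime `tau` must be positive and finite (ns)", call. = FALSE)
  }
  num <- exp(-gate$s / tau) - exp(-(gate$s + gate$W) / tau)
  den <- 1 - exp(-gate$T / tau)
  # large tau: both terms -> 0; expand to first order to avoid 0/0
  tiny <- den < 1e-12
  if (any(tiny)) {
    num[tiny] <- gate$W / tau[tiny]
    den[tiny] <- gate$T / tau[tiny]
  }
  num / den
}
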