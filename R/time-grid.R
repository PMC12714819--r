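#' Uniform time grid over one laser period
#'
#' Constructs the sampling grid shared by the decay model, the simulator and
#' the fitters. The grid covers exactly one repetition period `[0, T)` of the
#' pulsed excitation with uniform spacing `dt`; all times are in nanoseconds.
#'
#' @param period_ns Laser repetition period T in ns (for an 80 MHz laser,
#'   T = 1/0.08 = 12.5 ns). Mutually exclusive with `rep_rate_MHz`.
#' @param dt Sample spacing in ns. The default is a quarter of the 17.6 ps
#'   gate-step resolution of the sensor, fine enough for quadrature checks
#'   against the closed forms.
#' @param rep_rate_MHz Repetition rate in MHz, used as T = 1000/rate when
#'   `period_ns` is missing.
#'
#' @return An object of class `time_grid`: a list with `t` (sample times, ns),
#'   `dt` (spacing, ns) and `T` (period, ns). The number of samples is
#'   `round(T/dt)`; `dt` is adjusted so the samples tile the period exactly.
#' @examples
#' g <- time_grid(period_ns = 12.5, dt = 0.01)
#' length(g$t)
#' @export
time_grid <- function(period_ns = NULL, dt = 0.0176 / 4, rep_rate_MHz = NULL) {
  if (is.null(period_ns)) {
    if (is.null(rep_rate_MHz)) {
      stop("supply either `period_ns` or `rep_rate_MHz`", call. = FALSE)
    }
    period_ns <- 1000 / rep_rate_MHz
  }
  stopifnot(is.numeric(period_ns), length(period_ns) == 1L, period_ns > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0, dt < period_ns)
  n <- max(2L, as.integer(round(period_ns / dt)))
  dt <- period_ns / n
  structure(
    list(t = (seq_len(n) - 1) * dt, dt = dt, T = period_ns),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> T = %g ns, dt = %g ps, %d samples\n",
              x$T, x$dt * 1000, length(x$t)))
  invisible(x)
}

is_time_grid <- function(x) inherits(x, "time_grid")

same_grid <- function(a, b) {
  is_time_grid(a) && is_time_grid(b) &&
    length(a$t) == length(b$t) &&
    isTRUE(all.equal(a$T, b$T)) && isTRUE(all.equal(a$dt, b$dt))
}

#' One period of a T-periodic sampled signal
#'
#' Container used for decays, instrument response functions and recorded
#' signals: a vector of samples on a [time_grid()] plus a role tag.
#'
#' @param values Numeric vector of samples, one per grid point; all finite.
#' @param grid A [time_grid()].
#' @param label Role tag, one of `"decay"`, `"irf"`, `"recorded"`, `"pulse"`,
#'   `"gate"`.
#' @return An object of class `periodic_signal` with fields `values`, `grid`,
#'   `label`.
#' @export
periodic_signal <- function(values, grid,
                            label = c("decay", "irf", "recorded",
                                      "pulse", "gate")) {
  label <- match.arg(label)
  stopifnot(is_time_grid(grid))
  values <- as.numeric(values)
  if (length(values) != length(grid$t)) {
    stop("signal length does not match the time grid", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("periodic signal values must be finite", call. = FALSE)
  }
  structure(list(values = values, grid = grid, label = label),
            class = "periodic_signal")
}

#' @export
print.periodic_signal <- function(x, ...) {
  cat(sprintf("<periodic_signal:%s> %d samples on [0, %g) ns, range [%g, %g]\n",
              x$label, length(x$values), x$grid$T,
              min(x$values), max(x$values)))
  invisible(x)
}

# Integral of a periodic signal over its full period. The rectangle rule is
# exact for the smooth part of a periodic function; the linear-extrapolation
# endpoint correction accounts for the jump a truncated decay has at the wrap.
periodic_integral <- function(signal) {
  v <- signal$values
  n <- length(v)
  dt <- signal$grid$dt
  v_end <- if (n >= 2) 2 * v[n] - v[n - 1] else v[n]
  dt * (sum(v) - v[1] / 2 + v_end / 2)
}

#' Excitation pulse profile
#'
#' A non-negative, unit-area pulse shape sampled on a period grid. Used as the
#' laser temporal profile in the forward model.
#'
#' @param grid A [time_grid()].
#' @param shape `"delta"` (all mass in the first sample), `"gaussian"`, or
#'   `"sampled"` (user-supplied `values`).
#' @param fwhm_ps Full width at half maximum in picoseconds for the Gaussian
#'   shape.
#' @param center_ns Center of the Gaussian pulse in ns.
#' @param values Samples for `shape = "sampled"`; normalized to unit area.
#' @return A `periodic_signal` with label `"pulse"` and unit integral.
#' @export
pulse_profile <- function(grid, shape = c("delta", "gaussian", "sampled"),
                          fwhm_ps = 100, center_ns = 0.5, values = NULL) {
  shape <- match.arg(shape)
  stopifnot(is_time_grid(grid))
  v <- switch(shape,
    delta = {
      out <- numeric(length(grid$t))
      out[1] <- 1 / grid$dt
      out
    },
    gaussian = {
      sigma <- fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))
      stats::dnorm(grid$t, mean = center_ns, sd = sigma)
    },
    sampled = {
      if (is.null(values)) stop("`values` required for sampled pulse",
                                call. = FALSE)
      as.numeric(values)
    }
  )
  if (any(v < 0)) stop("pulse profile must be non-negative", call. = FALSE)
  area <- sum(v) * grid$dt
  if (area <= 0) stop("pulse profile has zero area", call. = FALSE)
  periodic_signal(v / area, grid, label = "pulse")
}

#' Detector single-photon timing response
#'
#' The detector's response to a single photon (jitter/walk kernel), sampled on
#' the period grid and normalized to unit area. Convolved with the excitation
#' pulse this gives the global instrument response function.
#'
#' @inheritParams pulse_profile
#' @return A `periodic_signal` with label `"irf"` and unit integral.
#' @export
detector_response <- function(grid, shape = c("delta", "gaussian", "sampled"),
                              fwhm_ps = 150, center_ns = 0.25, values = NULL) {
  p <- pulse_profile(grid, shape, fwhm_ps = fwhm_ps, center_ns = center_ns,
                     values = values)
  p$label <- "irf"
  p
}
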