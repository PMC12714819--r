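#' Complementary gate image
#'
#' The complementary gate counts `G1 = INT - G2`, non-negative under the
#' sensor contract.
#'
#' @param pair A [count_image_pair()].
#' @return Integer matrix of G1 counts.
#' @export
complementary_gate <- function(pair) {
  stopifnot(inherits(pair, "count_image_pair"))
  if (any(pair$g2 > pair$int_)) {
    stop("input violates the sensor contract: g2 > int_ somewhere",
         call. = FALSE)
  }
  pair$int_ - pair$g2
}

#' Dark-count and saturation correction
#'
#' Converts raw accumulated counts to estimated linear signal: first the
#' expected dark contribution is subtracted (`DCR * F * frame_exposure`,
#' scaled by `W/T` for the G2 channel, since dark counts are uniform in
#' time), then the binomial pile-up compression is inverted with
#' `lambda_hat = -F * log(1 - counts/F)` (counts clipped to `F - 1`). The
#' correction is monotone in the input, and for `counts << F` with no dark
#' counts it changes the counts by under 1%.
#'
#' @param pair [count_image_pair()].
#' @param dcr_map Per-pixel dark count rate (counts/s); scalar or matrix.
#' @param config [sensor_config()] carrying `F` and `frame_exposure`.
#' @return List with real-valued `g2` and `int_` corrected images (clamped
#'   at 0) plus the original `gate` and `F`.
#' @export
dark_saturation_correct <- function(pair, dcr_map = NULL, config) {
  stopifnot(inherits(pair, "count_image_pair"),
            inherits(config, "sensor_config"))
  F <- pair$F
  if (any(pair$int_ > F)) stop("counts exceed the frame budget F",
                               call. = FALSE)
  if (is.null(dcr_map)) dcr_map <- config$dcr_map
  if (length(dcr_map) == 1L) {
    dcr_map <- matrix(dcr_map, nrow(pair$int_), ncol(pair$int_))
  }
  dark_int <- dcr_map * F * config$frame_exposure
  dark_g2 <- dark_int * pair$gate$W / pair$gate$T
  desat <- function(counts) {
    x <- pmin(counts, F - 1) / F
    -F * log1p(-x)
  }
  g2 <- pmax(desat(pair$g2) - dark_g2, 0)
  int_ <- pmax(desat(pair$int_) - dark_int, 0)
  list(g2 = g2, int_ = int_, gate = pair$gate, F = F)
}

#' Build the lifetime-to-ratio lookup table
#'
#' Evaluates the expected G2/INT ratio on a log-spaced lifetime grid for a
#' fixed gate and validates that the mapping is strictly monotone over the
#' range (it is decreasing for an `s = 0` gate and increasing for a late
#' gate over practical ranges). The table is inverted by piecewise-linear
#' interpolation in [invert_ratio()]; log spacing equalizes the relative
#' interpolation error across the range.
#'
#' @param gate [gate_window()].
#' @param tau_min,tau_max Lifetime range in ns (default 0.1 to 10).
#' @param n_points Number of table points (default 4096).
#' @return An object of class `ratio_lut` with fields `tau_grid`, `r_grid`,
#'   `gate`, `direction` (`"increasing"` or `"decreasing"` in tau).
#' @examples
#' lut <- build_lut(gate_window(5.5, 3, 12.5))
#' lut$direction
#' @export
build_lut <- function(gate, tau_min = 0.1, tau_max = 10, n_points = 4096) {
  stopifnot(inherits(gate, "gate_window"),
            tau_min > 0, tau_max > tau_min, n_points >= 2)
  tau_grid <- exp(seq(log(tau_min), log(tau_max), length.out = n_points))
  r_grid <- gate_ratio(tau_grid, gate)
  d <- diff(r_grid)
  if (all(d > 0)) {
    direction <- "increasing"
  } else if (all(d < 0)) {
    direction <- "decreasing"
  } else {
    i <- which(d * d[1] <= 0)[1]
    stop(sprintf(
      paste0("ratio is not strictly monotone over [%g, %g] ns ",
             "(first reversal near tau = %.4g ns); narrow the range"),
      tau_min, tau_max, tau_grid[i]), call. = FALSE)
  }
  structure(list(tau_grid = tau_grid, r_grid = r_grid, gate = gate,
                 direction = direction),
            class = "ratio_lut")
}

#' @export
print.ratio_lut <- function(x, ...) {
  cat(sprintf(
    "<ratio_lut> %d points, tau in [%g, %g] ns, R in [%.4g, %.4g] (%s)\n",
    length(x$tau_grid), min(x$tau_grid), max(x$tau_grid),
    min(x$r_grid), max(x$r_grid), x$direction))
  invisible(x)
}

#' Invert measured ratios to lifetimes
#'
#' Monotone piecewise-linear interpolation of lifetime against ratio.
#' Ratios outside the table's range are returned as `NA` (masked), never
#' silently clamped to the range edges.
#'
#' @param r Numeric scalar, vector or matrix of measured G2/INT ratios.
#' @param lut A [build_lut()] table.
#' @return Lifetimes in ns, same shape as `r`; `NA` where out of range.
#' @export
invert_ratio <- function(r, lut) {
  stopifnot(inherits(lut, "ratio_lut"))
  dims <- dim(r)
  rv <- as.numeric(r)
  x <- lut$r_grid
  y <- lut$tau_grid
  if (lut$direction == "decreasing") {
    x <- rev(x); y <- rev(y)
  }
  out <- rep(NA_real_, length(rv))
  ok <- is.finite(rv) & rv >= x[1] & rv <= x[length(x)]
  if (any(ok)) {
    out[ok] <- stats::approx(x, y, xout = rv[ok], ties = "ordered")$y
  }
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Per-pixel lifetime map from one (G2, INT) snapshot
#'
#' The single-snapshot RLD pipeline: optional dark/saturation correction,
#' per-pixel ratio `R = G2 / INT`, lookup-table inversion to lifetime.
#' Pixels with fewer than `min_counts` raw INT counts are masked invalid
#' (the default of 10 marks the regime where ratio estimates are dominated
#' by noise), as are pixels whose ratio falls outside the table range.
#'
#' @param pair [count_image_pair()] (or a noiseless expected-count list from
#'   [simulate_pair()]).
#' @param lut [build_lut()] table; its gate must match the pair's gate.
#' @param min_counts Minimum raw INT counts for a valid pixel (default 10).
#' @param config [sensor_config()]; required when `correct = TRUE`.
#' @param dcr_map Optional per-pixel dark count rate for the correction.
#' @param offset_map Optional per-pixel effective gate-delay offset (ns): a
#'   calibration map of time-of-flight shifts. Each distinct offset gets its
#'   own shifted-gate lookup table.
#' @param correct Apply [dark_saturation_correct()] before forming ratios.
#' @return An object of class `lifetime_map`: `tau` (ns, `NA` where
#'   invalid), `valid` (logical), `r` (ratio), `counts_int` (raw INT
#'   counts), `n_masked`.
#' @export
estimate_map <- function(pair, lut, min_counts = 10, config = NULL,
                         dcr_map = NULL, offset_map = NULL,
                         correct = !is.null(config)) {
  stopifnot(inherits(lut, "ratio_lut"))
  if (!same_gate(pair$gate, lut$gate)) {
    stop("the lookup table was built for a different gate than the pair",
         call. = FALSE)
  }
  counts_int <- pair$int_
  if (correct) {
    if (is.null(config)) {
      stop("`config` is required for dark/saturation correction",
           call. = FALSE)
    }
    corr <- dark_saturation_correct(
      if (inherits(pair, "count_image_pair")) pair else
        count_image_pair(pair$g2, pair$int_, pair$F, pair$gate),
      dcr_map = dcr_map, config = config)
    g2 <- corr$g2; int_ <- corr$int_
  } else {
    g2 <- pair$g2; int_ <- pair$int_
  }
  r <- matrix(NA_real_, nrow(int_), ncol(int_))
  pos <- int_ > 0
  r[pos] <- g2[pos] / int_[pos]

  if (is.null(offset_map)) {
    tau <- invert_ratio(r, lut)
  } else {
    offset_map <- as.matrix(offset_map)
    stopifnot(all(dim(offset_map) == dim(r)))
    tau <- matrix(NA_real_, nrow(r), ncol(r))
    for (off in unique(as.numeric(offset_map))) {
      idx <- offset_map == off
      g <- lut$gate
      shifted <- gate_window(max(g$s - off, 0), g$W, g$T)
      lut_off <- build_lut(shifted, min(lut$tau_grid), max(lut$tau_grid),
                           length(lut$tau_grid))
      tau[idx] <- invert_ratio(r[idx], lut_off)
    }
  }

  valid <- pos & (counts_int >= min_counts) & is.finite(tau)
  tau[!valid] <- NA_real_
  structure(list(tau = tau, valid = valid, r = r, counts_int = counts_int,
                 n_masked = sum(!valid)),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf(
    "<lifetime_map> %d x %d px, %d valid (%.1f%%), mean tau %.3f ns\n",
    nrow(x$tau), ncol(x$tau), sum(x$valid),
    100 * mean(x$valid), mean(x$tau, na.rm = TRUE)))
  invisible(x)
}

#' Intensity-weighted lifetime image
#'
#' Lifetime (or lifetime-change) values weighted by the INT counts scaled to
#' `[0, 1]` — the standard display that suppresses dim, unreliable pixels.
#' Invalid pixels map to 0.
#'
#' @param map A [estimate_map()] result.
#' @param values Optional matrix to weight instead of `map$tau` (e.g. a
#'   delta-tau/tau map).
#' @return Matrix of weighted values.
#' @export
intensity_weighted_map <- function(map, values = NULL) {
  stopifnot(inherits(map, "lifetime_map"))
  v <- if (is.null(values)) map$tau else as.matrix(values)
  w <- map$counts_int
  mx <- max(w)
  w <- if (mx > 0) w / mx else w * 0
  out <- v * w
  out[!map$valid | !is.finite(out)] <- 0
  out
}

#' Shot-noise precision study of the RLD estimator
#'
#' For each photon budget (expected total detected photons per pixel per
#' acquisition), simulates repeated single-snapshot pairs at a known
#' lifetime, estimates the lifetime by ratio inversion, and reports bias and
#' standard deviation. In the Poisson-limited regime the standard deviation
#' scales as one over the square root of the collected counts, i.e. the
#' fitted slope of log(sd) versus log(mean INT counts) is -1/2.
#'
#' @param gate [gate_window()].
#' @param tau True lifetime (ns).
#' @param photon_budgets Expected detected photons per pixel per acquisition
#'   (vector spanning at least 1.5 decades for a meaningful slope).
#' @param n_repeats Repeats per budget.
#' @param config [sensor_config()]; choose `F` large enough that the
#'   per-frame bit probability stays well below 1 at the largest budget,
#'   otherwise pile-up (not shot noise) dominates.
#' @param lut Optional pre-built [build_lut()] for the gate.
#' @param seed Integer seed.
#' @return List with `table` (data.frame: budget, mean_int_counts, mean_tau,
#'   bias, sd, n) and `slope` (fitted log-log slope of sd vs mean counts).
#' @export
precision_study <- function(gate, tau, photon_budgets, n_repeats = 1000,
                            config, lut = NULL, seed = NULL) {
  stopifnot(inherits(gate, "gate_window"), inherits(config, "sensor_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(lut)) lut <- build_lut(gate)
  F <- config$F
  R <- gate_ratio(tau, gate)
  rows <- lapply(photon_budgets, function(budget) {
    p_total <- budget / F
    if (p_total >= 1) {
      stop(sprintf("budget %g exceeds the frame budget F = %d", budget, F),
           call. = FALSE)
    }
    # per-frame Bernoulli rates giving the requested expected counts
    lam_t <- -log(1 - p_total)            # detections per frame (period)
    lam_g <- R * lam_t                    # gated share of the Poisson rate
    p_gate <- 1 - exp(-lam_g)
    g2 <- stats::rbinom(n_repeats, F, p_gate)
    extra <- stats::rbinom(n_repeats, F - g2,
                           (p_total - p_gate) / (1 - p_gate))
    int_ <- g2 + extra
    # invert pile-up per channel, then form the ratio
    g2c <- -F * log1p(-pmin(g2, F - 1) / F)
    intc <- -F * log1p(-pmin(int_, F - 1) / F)
    r <- ifelse(intc > 0, g2c / intc, NA_real_)
    tau_hat <- invert_ratio(r, lut)
    ok <- is.finite(tau_hat) & int_ >= 1
    data.frame(budget = budget,
               mean_int_counts = mean(int_),
               mean_tau = mean(tau_hat[ok]),
               bias = mean(tau_hat[ok]) - tau,
               sd = stats::sd(tau_hat[ok]),
               n = sum(ok))
  })
  table <- do.call(rbind, rows)
  fit <- stats::lm(log(sd) ~ log(mean_int_counts), data = table)
  list(table = table, slope = unname(stats::coef(fit)[2]))
}
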