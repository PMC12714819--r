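#' Dual-gate SPAD sensor configuration
#'
#' Parameters of the binary-frame dual-gate acquisition: every 1-bit frame
#' integrates N consecutive laser pulses; a photon detected inside the gate
#' sets the G2 bit, a photon detected anywhere in the period sets the INT
#' bit; F one-bit frames are accumulated into the count images. The hardware
#' bit-depth presets are 12-bit (F = 4096 frames) and 10-bit (F = 4 x 255 =
#' 1020 frames).
#'
#' @param shape Integer vector `c(rows, cols)` of the simulated array.
#' @param bit_depth One of 8, 10, 12, or `NA` to set `F` directly. 12-bit
#'   accumulates 4096 frames, 10-bit 1020 (4 x 255), 8-bit 255.
#' @param F Frames accumulated per count image; derived from `bit_depth`
#'   unless given explicitly.
#' @param N Laser pulses integrated per 1-bit frame.
#' @param pde Photon detection efficiency in (0, 1].
#' @param dcr_map Per-pixel dark count rate (counts/s): scalar or matrix of
#'   `shape`; see [make_dcr_map()].
#' @param frame_exposure Exposure of one 1-bit frame in seconds. Default
#'   30.72 us.
#' @param jitter_fwhm_rise,jitter_fwhm_fall Gate-edge timing jitter FWHM in
#'   ps (defaults 109 and 153).
#' @param jitter_mode `"none"` (ideal edges), `"per_frame"` (fresh random
#'   edges each 1-bit frame) or `"static"` (one random edge pair per
#'   acquisition).
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(shape = c(32L, 32L), bit_depth = 10,
                          F = NULL, N = 1228L, pde = 0.15,
                          dcr_map = 0, frame_exposure = 30.72e-6,
                          jitter_fwhm_rise = 109, jitter_fwhm_fall = 153,
                          jitter_mode = c("none", "per_frame", "static")) {
  jitter_mode <- match.arg(jitter_mode)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  shape <- as.integer(shape)
  if (is.null(F)) {
    if (is.na(bit_depth)) stop("give either `bit_depth` or `F`", call. = FALSE)
    F <- switch(as.character(bit_depth),
                "12" = 4096L, "10" = 1020L, "8" = 255L,
                stop("bit_depth must be 8, 10 or 12", call. = FALSE))
  }
  F <- as.integer(F)
  stopifnot(F >= 1L, N >= 1L, pde > 0, pde <= 1,
            frame_exposure > 0,
            jitter_fwhm_rise >= 0, jitter_fwhm_fall >= 0)
  if (length(dcr_map) == 1L) {
    dcr_map <- matrix(dcr_map, shape[1], shape[2])
  }
  dcr_map <- as.matrix(dcr_map)
  if (!all(dim(dcr_map) == shape)) {
    stop("dcr_map dimensions do not match the sensor shape", call. = FALSE)
  }
  if (any(dcr_map < 0)) stop("dark count rates must be >= 0", call. = FALSE)
  structure(list(shape = shape, bit_depth = bit_depth, F = F,
                 N = as.integer(N), pde = pde, dcr_map = dcr_map,
                 frame_exposure = frame_exposure,
                 jitter_fwhm_rise = jitter_fwhm_rise,
                 jitter_fwhm_fall = jitter_fwhm_fall,
                 jitter_mode = jitter_mode),
            class = "sensor_config")
}

#' Per-pixel scene: amplitude, lifetime and optional time offset
#'
#' @param A0 Matrix of expected detected photons per laser period at unit
#'   detection efficiency (>= 0).
#' @param tau Matrix (or scalar) of lifetimes in ns; must be > 0 wherever
#'   `A0 > 0`.
#' @param offset Optional matrix (or scalar) of per-pixel time-of-flight
#'   offsets in ns (decay start shifted later by this amount); in `[0, T)`.
#' @return An object of class `scene_map`.
#' @export
scene_map <- function(A0, tau, offset = 0) {
  A0 <- as.matrix(A0)
  if (length(tau) == 1L) tau <- matrix(tau, nrow(A0), ncol(A0))
  tau <- as.matrix(tau)
  if (length(offset) == 1L) offset <- matrix(offset, nrow(A0), ncol(A0))
  offset <- as.matrix(offset)
  stopifnot(all(dim(tau) == dim(A0)), all(dim(offset) == dim(A0)))
  if (any(A0 < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(tau[A0 > 0] <= 0)) {
    stop("lifetimes must be > 0 wherever the amplitude is > 0", call. = FALSE)
  }
  if (any(offset < 0)) stop("time offsets must be >= 0", call. = FALSE)
  structure(list(A0 = A0, tau = tau, offset = offset), class = "scene_map")
}

#' Correlated G2/INT count image pair
#'
#' The single-snapshot datum: the gated (G2) and full-period (INT) count
#' images accumulated over the same F one-bit frames, with the hardware
#' contract `0 <= g2 <= int_ <= F` elementwise (a frame outcome of
#' G2 = 1 with INT = 0 is impossible).
#'
#' @param g2,int_ Integer count matrices of equal dimension.
#' @param F Frame budget.
#' @param gate The [gate_window()] used for G2.
#' @return An object of class `count_image_pair`.
#' @export
count_image_pair <- function(g2, int_, F, gate) {
  g2 <- as.matrix(g2); int_ <- as.matrix(int_)
  stopifnot(all(dim(g2) == dim(int_)), inherits(gate, "gate_window"))
  F <- as.integer(F)
  if (any(g2 < 0) || any(int_ > F) || any(g2 > int_)) {
    stop("count pair violates the sensor contract 0 <= g2 <= int_ <= F",
         call. = FALSE)
  }
  structure(list(g2 = g2, int_ = int_, F = F, gate = gate),
            class = "count_image_pair")
}

#' @export
print.count_image_pair <- function(x, ...) {
  cat(sprintf(
    "<count_image_pair> %d x %d px, F = %d; mean INT %.1f, mean G2 %.1f\n",
    nrow(x$int_), ncol(x$int_), x$F, mean(x$int_), mean(x$g2)))
  invisible(x)
}

# Expected detected photons per pulse inside the gate / the whole period for
# one pixel, including the uniform-in-time dark contribution.
pixel_rates <- function(A0, tau, offset, gate, config) {
  if (A0 > 0) {
    s_eff <- gate$s - offset
    # decay launched at t = offset; gate integral of A0 exp(-(t-offset)/tau)
    lam_g <- A0 * tau * (exp(-max(s_eff, 0) / tau) -
                           exp(-max(s_eff + gate$W, 0) / tau))
    lam_t <- A0 * tau * (1 - exp(-(gate$T - offset) / tau))
  } else {
    lam_g <- 0
    lam_t <- 0
  }
  list(gate = config$pde * lam_g, total = config$pde * lam_t)
}

#' Per-frame detection probabilities for one pixel
#'
#' Expected detected photons per pulse are `lambda_g = pde * S_G2 + dark`
#' inside the gate and `lambda_t = pde * S_INT + dark` over the period; with
#' N pulses per 1-bit frame the probability that the frame bit is set is
#' `p = 1 - exp(-N * lambda)` (at least one detection).
#'
#' @param A0,tau,offset Scene values for the pixel (see [scene_map()]).
#' @param dcr Dark count rate for the pixel (counts/s).
#' @param gate [gate_window()].
#' @param config [sensor_config()].
#' @return List with `p_gate` and `p_total`, `0 <= p_gate <= p_total <= 1`.
#' @export
per_frame_probabilities <- function(A0, tau, offset = 0, dcr = 0,
                                    gate, config) {
  stopifnot(inherits(gate, "gate_window"), inherits(config, "sensor_config"))
  r <- pixel_rates(A0, tau, offset, gate, config)
  dark_per_pulse <- dcr * config$frame_exposure / config$N
  lam_g <- r$gate + dark_per_pulse * gate$W / gate$T
  lam_t <- r$total + dark_per_pulse
  list(p_gate = 1 - exp(-config$N * lam_g),
       p_total = 1 - exp(-config$N * lam_t))
}

# Vectorized frame-bit probabilities for a whole scene.
scene_probabilities <- function(scene, gate, config) {
  dims <- dim(scene$A0)
  p_gate <- matrix(0, dims[1], dims[2])
  p_total <- matrix(0, dims[1], dims[2])
  tau <- scene$tau; A0 <- scene$A0; off <- scene$offset
  s_eff <- gate$s - off
  lam_g <- ifelse(A0 > 0,
                  A0 * tau * (exp(-pmax(s_eff, 0) / tau) -
                                exp(-pmax(s_eff + gate$W, 0) / tau)),
                  0)
  lam_t <- ifelse(A0 > 0,
                  A0 * tau * (1 - exp(-(gate$T - off) / tau)),
                  0)
  dark_per_pulse <- config$dcr_map * config$frame_exposure / config$N
  lam_g <- config$pde * lam_g + dark_per_pulse * gate$W / gate$T
  lam_t <- config$pde * lam_t + dark_per_pulse
  list(p_gate = 1 - exp(-config$N * lam_g),
       p_total = 1 - exp(-config$N * lam_t))
}

#' Gate with randomly jittered edges
#'
#' Shifts the rising edge by N(0, sigma_rise) and the falling edge by
#' N(0, sigma_fall), with sigma = FWHM / 2.3548, then clips the window to
#' `[0, T]`. Models the stochastic timing uncertainty of the gate edges.
#'
#' @param gate [gate_window()].
#' @param config [sensor_config()] carrying the edge-jitter FWHMs (ps).
#' @return A new `gate_window` with perturbed edges.
#' @export
jittered_gate <- function(gate, config) {
  stopifnot(inherits(gate, "gate_window"), inherits(config, "sensor_config"))
  fw2sd <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548
  sr <- config$jitter_fwhm_rise / 1000 * fw2sd
  sf <- config$jitter_fwhm_fall / 1000 * fw2sd
  rise <- gate$s + if (sr > 0) stats::rnorm(1, 0, sr) else 0
  fall <- gate$s + gate$W + if (sf > 0) stats::rnorm(1, 0, sf) else 0
  rise <- min(max(rise, 0), gate$T)
  fall <- min(max(fall, 0), gate$T)
  if (fall <= rise) fall <- rise + 1e-6
  gate_window(rise, fall - rise, gate$T)
}

#' Simulate one correlated (G2, INT) snapshot
#'
#' Draws F one-bit frames per pixel under the dual-gate contract: each frame
#' jointly samples (INT bit, G2 bit) with `P(G2=1) = p_gate`,
#' `P(INT=1) = p_total` and `P(G2=1, INT=0) = 0`. The accumulated counts
#' follow the exact nested-binomial factorization
#' `g2 ~ Binomial(F, p_gate)` and
#' `int_ = g2 + Binomial(F - g2, (p_total - p_gate)/(1 - p_gate))`,
#' which reproduces the per-frame joint law without per-pulse simulation.
#' Saturation (counts compressing towards F as p approaches 1) emerges from
#' the binomial model itself.
#'
#' @param scene [scene_map()].
#' @param gate [gate_window()].
#' @param config [sensor_config()]. With `jitter_mode != "none"` the gate
#'   edges are redrawn (per frame or once) before computing probabilities.
#' @param seed Integer seed; required for reproducibility.
#' @param noiseless If TRUE, return expected counts `F * p` (real-valued, in
#'   a plain list) instead of sampling.
#' @return A [count_image_pair()] (or list `g2`, `int_` of expected counts
#'   when `noiseless = TRUE`).
#' @export
simulate_pair <- function(scene, gate, config, seed = NULL,
                          noiseless = FALSE) {
  stopifnot(inherits(scene, "scene_map"), inherits(gate, "gate_window"),
            inherits(config, "sensor_config"))
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  npix <- prod(config$shape)
  if (!all(dim(scene$A0) == config$shape)) {
    stop("scene dimensions do not match the sensor shape", call. = FALSE)
  }

  if (noiseless) {
    p <- scene_probabilities(scene, gate, config)
    return(list(g2 = config$F * p$p_gate, int_ = config$F * p$p_total,
                F = config$F, gate = gate))
  }

  if (config$jitter_mode == "none") {
    p <- scene_probabilities(scene, gate, config)
    g2 <- stats::rbinom(npix, config$F, p$p_gate)
    extra_p <- ifelse(p$p_gate < 1,
                      (p$p_total - p$p_gate) / (1 - p$p_gate), 0)
    extra_p <- pmin(pmax(extra_p, 0), 1)
    int_ <- g2 + stats::rbinom(npix, config$F - g2, extra_p)
  } else if (config$jitter_mode == "static") {
    p <- scene_probabilities(scene, jittered_gate(gate, config), config)
    g2 <- stats::rbinom(npix, config$F, p$p_gate)
    extra_p <- ifelse(p$p_gate < 1,
                      (p$p_total - p$p_gate) / (1 - p$p_gate), 0)
    extra_p <- pmin(pmax(extra_p, 0), 1)
    int_ <- g2 + stats::rbinom(npix, config$F - g2, extra_p)
  } else {
    # fresh gate edges every 1-bit frame (edges are global across the array)
    g2 <- integer(npix); int_ <- integer(npix)
    for (f in seq_len(config$F)) {
      p <- scene_probabilities(scene, jittered_gate(gate, config), config)
      gbit <- stats::rbinom(npix, 1L, p$p_gate)
      extra_p <- ifelse(p$p_gate < 1,
                        (p$p_total - p$p_gate) / (1 - p$p_gate), 0)
      extra_p <- pmin(pmax(extra_p, 0), 1)
      ibit <- gbit + stats::rbinom(npix, 1L - gbit, extra_p)
      g2 <- g2 + gbit
      int_ <- int_ + ibit
    }
  }
  count_image_pair(matrix(g2, config$shape[1], config$shape[2]),
                   matrix(int_, config$shape[1], config$shape[2]),
                   config$F, gate)
}

#' Simulate a gate-scanned decay acquisition
#'
#' One (G2, INT) pair per gate delay, with the delay stepped across the
#' period in multiples of the 17.6 ps gate-step resolution. Noise is drawn
#' independently per acquisition, so a full scan costs `length(delays)` times
#' the photon budget of a single snapshot.
#'
#' @param scene [scene_map()].
#' @param gate_width Gate width W in ns.
#' @param delays Gate offsets s in ns (non-negative; each a multiple of
#'   0.0176 ns unless `allow_any_delay = TRUE`).
#' @param config [sensor_config()].
#' @param seed Integer seed.
#' @param period_ns Laser period T in ns (default 12.5, i.e. 80 MHz).
#' @param allow_any_delay Skip the gate-step-multiple validation.
#' @param noiseless Propagated to [simulate_pair()].
#' @return A list of class `decay_scan`: `pairs` (one per delay), `delays`,
#'   `gate_width`, `period_ns`, `config`.
#' @export
simulate_decay_scan <- function(scene, gate_width, delays, config,
                                seed = NULL, period_ns = 12.5,
                                allow_any_delay = FALSE,
                                noiseless = FALSE) {
  stopifnot(is.numeric(delays), length(delays) >= 1L, all(delays >= 0))
  step <- 0.0176
  if (!allow_any_delay) {
    k <- delays / step
    if (any(abs(k - round(k)) > 1e-6)) {
      stop(paste0("delays must be non-negative multiples of the 17.6 ps ",
                  "gate step (use allow_any_delay = TRUE to override)"),
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  pairs <- lapply(delays, function(s) {
    g <- gate_window(s, gate_width, period_ns)
    simulate_pair(scene, g, config, seed = NULL, noiseless = noiseless)
  })
  structure(list(pairs = pairs, delays = delays, gate_width = gate_width,
                 period_ns = period_ns, config = config),
            class = "decay_scan")
}

#' Log-normal dark count rate map with hot pixels
#'
#' Generates a spatially non-uniform per-pixel dark count rate field: a
#' log-normal background with the requested median, plus a random fraction of
#' hot pixels at `hot_scale` times the median.
#'
#' @param shape `c(rows, cols)`.
#' @param median_dcr Median dark count rate, counts/s.
#' @param hot_fraction Fraction of hot pixels in `[0, 1)`.
#' @param hot_scale Hot-pixel rate as a multiple of the median.
#' @param sdlog Log-scale spread of the background field.
#' @param seed Integer seed.
#' @return Matrix of dark count rates (counts/s).
#' @export
make_dcr_map <- function(shape, median_dcr = 100, hot_fraction = 0.01,
                         hot_scale = 100, sdlog = 0.5, seed = NULL) {
  stopifnot(hot_fraction >= 0, hot_fraction < 1, median_dcr >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- prod(shape)
  dcr <- stats::rlnorm(n, meanlog = log(max(median_dcr, 1e-12)),
                       sdlog = sdlog)
  if (median_dcr == 0) dcr <- rep(0, n)
  n_hot <- round(hot_fraction * n)
  if (n_hot > 0) {
    hot <- sample.int(n, n_hot)
    dcr[hot] <- hot_scale * median_dcr
  }
  matrix(dcr, shape[1], shape[2])
}
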