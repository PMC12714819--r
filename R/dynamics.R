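#' Lifetime video
#'
#' An ordered sequence of per-pixel lifetime maps at a fixed frame rate,
#' with the spatial calibration needed to express wavefront positions in
#' micrometers.
#'
#' @param frames List of lifetime matrices (ns; `NA` marks invalid pixels)
#'   or of [estimate_map()] results.
#' @param fps Frame rate, frames per second.
#' @param pixel_size Pixel pitch in micrometers.
#' @return An object of class `lifetime_video`.
#' @export
lifetime_video <- function(frames, fps, pixel_size) {
  stopifnot(length(frames) >= 1L, fps > 0, pixel_size > 0)
  frames <- lapply(frames, function(f) {
    if (inherits(f, "lifetime_map")) f$tau else as.matrix(f)
  })
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), logical(1)))) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size),
            class = "lifetime_video")
}

#' @export
print.lifetime_video <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<lifetime_video> %d frames of %d x %d px at %g fps (%g um/px)\n",
              length(x$frames), d[1], d[2], x$fps, x$pixel_size))
  invisible(x)
}

#' Pre-activation baseline lifetime map
#'
#' Per-pixel mean lifetime over the first `n_pre_frames` frames, ignoring
#' invalid (`NA`) pixels frame-wise. A pixel invalid in every baseline frame
#' stays invalid (`NA`).
#'
#' @param video A [lifetime_video()].
#' @param n_pre_frames Number of leading frames to average (>= 1 and <= the
#'   video length).
#' @return Matrix of baseline lifetimes (ns).
#' @export
baseline_map <- function(video, n_pre_frames) {
  stopifnot(inherits(video, "lifetime_video"))
  if (n_pre_frames < 1 || n_pre_frames > length(video$frames)) {
    stop("`n_pre_frames` must be between 1 and the number of frames",
         call. = FALSE)
  }
  pre <- video$frames[seq_len(n_pre_frames)]
  acc <- array(unlist(pre), dim = c(dim(pre[[1]]), n_pre_frames))
  out <- apply(acc, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  out
}

#' Baseline-relative lifetime change map
#'
#' The fractional lifetime change
#' `delta tau / tau = (tau_current - tau_baseline) / tau_baseline`,
#' the contrast used to visualize dynamic events such as calcium transients.
#' Invalid wherever either input is invalid or the baseline is not positive.
#'
#' @param frame_tau Matrix of current lifetimes (ns).
#' @param baseline_tau Matrix of baseline lifetimes (ns), same shape.
#' @return Matrix of signed fractional changes (`NA` where invalid).
#' @export
delta_tau_map <- function(frame_tau, baseline_tau) {
  frame_tau <- as.matrix(frame_tau)
  baseline_tau <- as.matrix(baseline_tau)
  stopifnot(all(dim(frame_tau) == dim(baseline_tau)))
  out <- (frame_tau - baseline_tau) / baseline_tau
  out[!is.finite(out) | baseline_tau <= 0] <- NA_real_
  out
}

#' Profile along an oriented rectangular ROI
#'
#' Mask-aware mean across the ROI's width at each position along its axis.
#' For `angle = 0` the axis runs along columns (left to right); a non-zero
#' angle (degrees, counter-clockwise) samples the rotated rectangle by
#' bilinear interpolation.
#'
#' @param map Matrix (e.g. a [delta_tau_map()]).
#' @param roi `c(row, col, length, width)` in pixels: the axis starts at
#'   (row, col) (1-based, the center of the width extent) and runs for
#'   `length` pixels; the mean is taken over `width` pixels across.
#' @param angle Axis orientation in degrees counter-clockwise from the
#'   column direction.
#' @return Numeric vector of length `roi[3]` (`NA` where no valid pixels).
#' @export
roi_profile <- function(map, roi, angle = 0) {
  map <- as.matrix(map)
  stopifnot(length(roi) == 4L, roi[3] >= 1, roi[4] >= 1)
  r0 <- roi[1]; c0 <- roi[2]; len <- roi[3]; wid <- roi[4]
  if (angle == 0) {
    rows <- r0 + seq_len(wid) - 1 - floor((wid - 1) / 2)
    cols <- c0 + seq_len(len) - 1
    if (min(rows) < 1 || max(rows) > nrow(map) ||
        min(cols) < 1 || max(cols) > ncol(map)) {
      stop("ROI extends outside the image", call. = FALSE)
    }
    sub <- map[rows, cols, drop = FALSE]
    return(apply(sub, 2, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }))
  }
  th <- angle * pi / 180
  ax <- c(sin(th), cos(th))    # (drow, dcol) along the axis
  px <- c(cos(th), -sin(th))   # perpendicular (across the width)
  offs <- seq_len(wid) - 1 - (wid - 1) / 2
  vapply(seq_len(len) - 1, function(j) {
    vals <- vapply(offs, function(k) {
      rr <- r0 + j * ax[1] + k * px[1]
      cc <- c0 + j * ax[2] + k * px[2]
      bilinear_sample(map, rr, cc)
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

bilinear_sample <- function(map, r, c) {
  if (r < 1 || c < 1 || r > nrow(map) || c > ncol(map)) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  r1 <- floor(r); c1 <- floor(c)
  r2 <- min(r1 + 1, nrow(map)); c2 <- min(c1 + 1, ncol(map))
  fr <- r - r1; fc <- c - c1
  v <- c(map[r1, c1], map[r1, c2], map[r2, c1], map[r2, c2])
  w <- c((1 - fr) * (1 - fc), (1 - fr) * fc, fr * (1 - fc), fr * fc)
  if (all(is.na(v))) return(NA_real_)
  sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)])
}

#' Halfway-point wavefront position along a profile
#'
#' Locates the wavefront as the first crossing of half the plateau value
#' along the propagation axis, with sub-pixel linear interpolation between
#' the bracketing samples. The plateau is estimated robustly as the median
#' of the top decile of the profile, so single-pixel outliers do not move
#' the threshold. Returns `NA` when the plateau does not exceed the noise
#' floor or no crossing exists within the profile.
#'
#' @param profile Numeric vector (e.g. from [roi_profile()]), ordered along
#'   the propagation direction; position 0 is the first sample.
#' @param pixel_size Pixel pitch in micrometers.
#' @param noise_floor Minimum plateau for a detection; typically 3x the
#'   pre-activation standard deviation of the profile. Default 0 (any
#'   positive plateau accepted).
#' @return Position in micrometers, or `NA` if no front is detectable.
#' @export
wavefront_position <- function(profile, pixel_size = 1, noise_floor = 0) {
  stopifnot(length(profile) >= 3L, pixel_size > 0)
  v <- profile
  ok <- is.finite(v)
  if (sum(ok) < 3L) return(NA_real_)
  plateau <- robust_plateau(v)
  if (!is.finite(plateau) || plateau <= noise_floor || plateau <= 0) {
    return(NA_real_)
  }
  thr <- plateau / 2
  # first threshold crossing (in either direction) along the axis; the
  # profile is elevated on the activated side of the front, so the crossing
  # marks the front whichever way the wave travels through the ROI
  for (i in 2:length(v)) {
    if (!ok[i] || !ok[i - 1]) next
    d1 <- v[i - 1] - thr
    d2 <- v[i] - thr
    if (d1 == 0) return((i - 2) * pixel_size)
    if (d1 * d2 < 0 || d2 == 0) {
      frac <- d1 / (d1 - d2)
      return(((i - 2) + frac) * pixel_size)
    }
  }
  NA_real_
}

# Robust plateau estimate of a profile: median of its top decile of values.
robust_plateau <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 3L) return(NA_real_)
  top <- stats::quantile(v, 0.9, names = FALSE)
  stats::median(v[v >= top])
}

#' Wavefront propagation speed by linear fit
#'
#' Ordinary least-squares slope of wavefront position versus time; frames
#' with no detected front (`NA` position) are excluded.
#'
#' @param positions Wavefront positions in micrometers (may contain `NA`).
#' @param times Frame times in seconds, same length.
#' @return List with `speed` (um/s), `se` (standard error of the slope) and
#'   `n` (points used).
#' @export
wavefront_speed <- function(positions, times) {
  stopifnot(length(positions) == length(times))
  ok <- is.finite(positions) & is.finite(times)
  if (sum(ok) < 3L) {
    stop("need at least 3 detected wavefront positions for a linear fit",
         call. = FALSE)
  }
  fit <- stats::lm(positions[ok] ~ times[ok])
  # summary.lm warns on exact fits; a zero standard error is a fine answer
  co <- suppressWarnings(summary(fit)$coefficients)
  list(speed = unname(co[2, 1]), se = unname(co[2, 2]), n = sum(ok))
}

#' Track a wavefront through a lifetime video
#'
#' Convenience pipeline: baseline over the pre-activation frames, per-frame
#' delta-tau/tau maps, ROI profiles, halfway-point localization, linear-fit
#' speed.
#'
#' @param video [lifetime_video()].
#' @param roi,angle ROI specification as in [roi_profile()].
#' @param n_pre_frames Baseline frames (excluded from tracking).
#' @param noise_floor_mult Noise floor as a multiple of the pre-activation
#'   profile standard deviation (default 3).
#' @param plateau_gate Fraction of the maximum per-frame plateau (over the
#'   whole video) a frame's plateau must reach for its halfway point to be
#'   used (default 0.9). While the front is still entering the ROI the
#'   plateau — and hence the halfway threshold — is not yet defined, so such
#'   frames are excluded from the fit.
#' @return An object of class `wavefront_track`: data.frame `track`
#'   (`time_s`, `position_um`), `speed_um_s`, `speed_se`, `n_detected`.
#' @export
track_wavefront <- function(video, roi, n_pre_frames, angle = 0,
                            noise_floor_mult = 3, plateau_gate = 0.9) {
  stopifnot(inherits(video, "lifetime_video"))
  base <- baseline_map(video, n_pre_frames)
  profiles <- lapply(video$frames, function(f) {
    roi_profile(delta_tau_map(f, base), roi, angle)
  })
  pre_sd <- stats::sd(unlist(profiles[seq_len(n_pre_frames)]), na.rm = TRUE)
  if (!is.finite(pre_sd)) pre_sd <- 0
  plateaus <- vapply(profiles, robust_plateau, numeric(1))
  max_plateau <- max(plateaus[-seq_len(n_pre_frames)], 0, na.rm = TRUE)
  floor_ <- max(noise_floor_mult * pre_sd, plateau_gate * max_plateau)
  idx <- seq_along(video$frames)
  times <- (idx - 1) / video$fps
  positions <- vapply(idx, function(i) {
    if (i <= n_pre_frames) return(NA_real_)
    wavefront_position(profiles[[i]], video$pixel_size,
                       noise_floor = floor_)
  }, numeric(1))
  sp <- wavefront_speed(positions, times)
  structure(list(track = data.frame(time_s = times,
                                    position_um = positions),
                 speed_um_s = sp$speed, speed_se = sp$se,
                 n_detected = sp$n),
            class = "wavefront_track")
}

#' @export
print.wavefront_track <- function(x, ...) {
  cat(sprintf(
    "<wavefront_track> %d detections, speed %.3f +/- %.3f um/s\n",
    x$n_detected, x$speed_um_s, x$speed_se))
  invisible(x)
}

#' Synthetic propagating calcium-wave lifetime video
#'
#' Generates a lifetime video emulating an intracellular calcium transient:
#' a sigmoidal lifetime-increase front of fractional amplitude `amplitude`
#' sweeping along the column axis at constant speed,
#' `tau(x, t) = tau0 * (1 + amplitude * sigmoid((v * t + x0 - x) / front_width))`,
#' plus optional Gaussian estimation noise. The front starts at `x0`
#' (negative: outside the field, so the leading frames are pure baseline).
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param n_frames Number of frames.
#' @param fps Frame rate (frames/s).
#' @param pixel_size Pixel pitch (um).
#' @param tau0 Baseline lifetime (ns).
#' @param amplitude Fractional lifetime change at the plateau (0.15 emulates
#'   a typical calcium transient).
#' @param speed Front speed (um/s).
#' @param front_width Sigmoid width parameter (um).
#' @param x0 Front position at t = 0 (um); default places it 8 sigmoid
#'   widths before the field so early frames are baseline.
#' @param noise_sd Gaussian noise added to each lifetime sample (ns).
#' @param seed Integer seed (used when `noise_sd > 0`).
#' @return A [lifetime_video()] with attribute `ground_truth` (list with
#'   `speed`, `amplitude`, `tau0`, `x0`).
#' @export
synth_calcium_wave <- function(shape = c(20L, 100L), n_frames = 16,
                               fps = 6.25, pixel_size = 0.25,
                               tau0 = 1, amplitude = 0.15,
                               speed = 7.47, front_width = 0.5,
                               x0 = -8 * front_width,
                               noise_sd = 0, seed = NULL) {
  stopifnot(tau0 > 0, speed != 0, front_width > 0, amplitude >= 0,
            noise_sd >= 0, fps > 0, pixel_size > 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- (seq_len(shape[2]) - 1) * pixel_size
  frames <- lapply(seq_len(n_frames) - 1, function(k) {
    t <- k / fps
    front <- speed * t + x0
    prof <- tau0 * (1 + amplitude * stats::plogis((front - x) / front_width))
    f <- matrix(prof, nrow = shape[1], ncol = shape[2], byrow = TRUE)
    if (noise_sd > 0) {
      f <- f + matrix(stats::rnorm(length(f), 0, noise_sd),
                      nrow = shape[1])
    }
    f
  })
  out <- lifetime_video(frames, fps, pixel_size)
  attr(out, "ground_truth") <- list(speed = speed, amplitude = amplitude,
                                    tau0 = tau0, x0 = x0)
  out
}
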