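test_that("baseline map averages valid frames per pixel", {
  f <- matrix(1, 4, 4)
  video <- lifetime_video(list(f, f * 1.0, f * 1.0, f * 3), fps = 6.25,
                          pixel_size = 1)
  expect_equal(baseline_map(video, 3), f)

  # one invalid frame among the baseline: mean over the valid ones
  f2 <- f; f2[2, 2] <- NA
  video2 <- lifetime_video(list(f, f2, f * 2, f * 3), fps = 6.25,
                           pixel_size = 1)
  b <- baseline_map(video2, 3)
  expect_equal(b[2, 2], (1 + 2) / 2)
  expect_equal(b[1, 1], (1 + 1 + 2) / 3)

  # pixel invalid in every baseline frame stays invalid
  f3 <- f; f3[1, 1] <- NA
  video3 <- lifetime_video(list(f3, f3), fps = 1, pixel_size = 1)
  expect_true(is.na(baseline_map(video3, 2)[1, 1]))

  expect_error(baseline_map(video, 0), "between")
  expect_error(baseline_map(video, 9), "between")
})

test_that("delta tau map is the signed fractional change", {
  cur <- matrix(1.15, 2, 2)
  base <- matrix(1.0, 2, 2)
  expect_equal(delta_tau_map(cur, base), matrix(0.15, 2, 2))
  expect_equal(delta_tau_map(base, base), matrix(0, 2, 2))
  expect_equal(delta_tau_map(matrix(0.8, 2, 2), base)[1, 1], -0.2)

  # invalid and zero-baseline pixels propagate as NA, no exception
  cur[1, 1] <- NA; base[2, 2] <- 0
  d <- delta_tau_map(cur, base)
  expect_true(is.na(d[1, 1]) && is.na(d[2, 2]))
})

test_that("roi profile averages across the width, mask-aware", {
  m <- matrix(rep(1:10, each = 5), nrow = 5)  # columns 1..10 hold 1..10
  p <- roi_profile(m, roi = c(3, 1, 10, 1))
  expect_equal(p, as.numeric(1:10))

  p3 <- roi_profile(m, roi = c(3, 2, 8, 3))
  expect_equal(p3, as.numeric(2:9))

  m[2, 4] <- NA
  p_na <- roi_profile(m, roi = c(3, 1, 10, 5))
  expect_equal(p_na[4], 4)  # mean of remaining valid pixels

  const <- matrix(2, 6, 6)
  expect_equal(roi_profile(const, c(3, 1, 6, 3)), rep(2, 6))

  # a 45-degree ROI across a column gradient sees sqrt(2)-spaced values
  g <- matrix(rep(1:20, each = 20), nrow = 20)
  p45 <- roi_profile(g, roi = c(2, 2, 10, 1), angle = 45)
  expect_equal(diff(p45), rep(cos(pi / 4), 9), tolerance = 1e-9)

  expect_error(roi_profile(m, c(1, 1, 50, 1)), "outside")
})

test_that("halfway-point localization is sub-pixel and noise-guarded", {
  # step from 0 to 0.15 between samples 11 and 12 (positions 10 and 11)
  prof <- c(rep(0, 11), rep(0.15, 10))
  expect_equal(wavefront_position(prof, pixel_size = 1), 10.5)

  expect_true(is.na(wavefront_position(rep(0, 30), 1)))
  expect_true(is.na(wavefront_position(rep(0.2, 30), 1)))  # no crossing

  # plateau below the noise floor: rejected
  expect_true(is.na(wavefront_position(prof, 1, noise_floor = 0.2)))

  # synthetic sigmoid front centred at 25 um, 1 um pixels
  x <- 0:49
  prof_sig <- 0.15 * plogis((25 - x) / 1.5)
  expect_equal(wavefront_position(prof_sig, 1), 25, tolerance = 0.25)

  # sub-pixel translation moves the estimate by the same amount
  prof_shift <- 0.15 * plogis((25.4 - x) / 1.5)
  expect_equal(wavefront_position(prof_shift, 1) -
                 wavefront_position(prof_sig, 1), 0.4, tolerance = 0.25)
})

test_that("wavefront speed is the least-squares slope with its se", {
  sp <- wavefront_speed(c(0, 7.47, 14.94), c(0, 1, 2))
  expect_equal(sp$speed, 7.47, tolerance = 1e-12)
  expect_equal(sp$se, 0, tolerance = 1e-9)

  set.seed(31)
  t <- seq(0, 2, by = 0.16)
  pos <- 7.47 * t + rnorm(length(t), 0, 0.2)
  spn <- wavefront_speed(pos, t)
  expect_lt(abs(spn$speed - 7.47), 3 * spn$se)

  # time reversal negates the slope
  rev_sp <- wavefront_speed(c(0, 7.47, 14.94), c(2, 1, 0))
  expect_equal(rev_sp$speed, -7.47, tolerance = 1e-12)

  expect_error(wavefront_speed(c(1, NA, NA, 2), 1:4), "at least 3")
})

test_that("synthetic wave generator honours its ground truth", {
  flat <- synth_calcium_wave(shape = c(4, 30), n_frames = 3,
                             amplitude = 0, tau0 = 2)
  for (f in flat$frames) expect_true(all(abs(f - 2) < 1e-12))

  wave <- synth_calcium_wave(shape = c(4, 60), n_frames = 12, tau0 = 1,
                             amplitude = 0.15, speed = 7.47,
                             pixel_size = 0.5)
  gt <- attr(wave, "ground_truth")
  expect_equal(gt$speed, 7.47)
  # late frame: plateau of delta tau / tau reaches the amplitude
  base <- baseline_map(wave, 1)
  d_late <- delta_tau_map(wave$frames[[12]], base)
  expect_equal(max(d_late, na.rm = TRUE), 0.15, tolerance = 5e-3)

  # determinism of the noisy variant under a fixed seed
  n1 <- synth_calcium_wave(noise_sd = 0.02, seed = 5)
  n2 <- synth_calcium_wave(noise_sd = 0.02, seed = 5)
  expect_identical(n1$frames, n2$frames)
})

test_that("end-to-end pipeline recovers the seeded propagation speed", {
  run <- function(speed, noise_sd = 0, seed = NULL, n_frames = 24) {
    video <- synth_calcium_wave(shape = c(20, 100), n_frames = n_frames,
                                fps = 6.25, pixel_size = 0.25, tau0 = 1,
                                amplitude = 0.15, speed = speed,
                                front_width = 0.5, noise_sd = noise_sd,
                                seed = seed)
    track_wavefront(video, roi = c(10, 1, 100, 16), n_pre_frames = 3)
  }

  # noise-free: the halfway-point + linear-fit pipeline is exact to < 1%
  tr <- run(7.47)
  expect_gte(tr$n_detected, 8)
  expect_lt(abs(tr$speed_um_s - 7.47) / 7.47, 0.01)

  # with realistic estimation noise the speed still lands within 5%
  trn <- run(7.47, noise_sd = 0.02, seed = 41)
  expect_lt(abs(trn$speed_um_s - 7.47) / 7.47, 0.05)

  # units audit: halving the frame rate doubles the apparent speed per
  # frame, i.e. speed scales as required by dimensional analysis
  video <- synth_calcium_wave(shape = c(20, 100), n_frames = 24,
                              fps = 6.25, pixel_size = 0.25,
                              speed = 7.47, front_width = 0.5)
  video_slow <- lifetime_video(video$frames, fps = 3.125,
                               pixel_size = 0.25)
  tr_slow <- track_wavefront(video_slow, c(10, 1, 100, 16), 3)
  expect_equal(tr_slow$speed_um_s, tr$speed_um_s / 2, tolerance = 1e-6)

  video_big <- lifetime_video(video$frames, fps = 6.25, pixel_size = 0.5)
  tr_big <- track_wavefront(video_big, c(10, 1, 100, 16), 3)
  expect_equal(tr_big$speed_um_s, tr$speed_um_s * 2, tolerance = 1e-6)

  # translation equivariance of detected positions
  v1 <- synth_calcium_wave(shape = c(8, 100), n_frames = 20, fps = 6.25,
                           pixel_size = 0.25, speed = 7.47,
                           front_width = 0.5, x0 = -4)
  v2 <- synth_calcium_wave(shape = c(8, 100), n_frames = 20, fps = 6.25,
                           pixel_size = 0.25, speed = 7.47,
                           front_width = 0.5, x0 = -2)
  t1 <- track_wavefront(v1, c(4, 1, 100, 8), 2)
  t2 <- track_wavefront(v2, c(4, 1, 100, 8), 2)
  both <- is.finite(t1$track$position_um) & is.finite(t2$track$position_um)
  shifts <- (t2$track$position_um - t1$track$position_um)[both]
  expect_true(all(abs(shifts - 2) <= 0.25 / 4 + 1e-9))
})
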