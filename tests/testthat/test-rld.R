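test_that("complementary gate is INT - G2 and non-negative", {
  g <- macro_gate()
  pair <- count_image_pair(matrix(30, 2, 2), matrix(100, 2, 2), 1020, g)
  expect_true(all(complementary_gate(pair) == 70))

  cfg <- small_config()
  scene <- uniform_scene(150, tau = 1.65, config = cfg, gate = g)
  p <- simulate_pair(scene, g, cfg, seed = 4)
  g1 <- complementary_gate(p)
  expect_true(all(g1 >= 0))
  expect_true(all(g1 + p$g2 == p$int_))

  same <- count_image_pair(matrix(5, 2, 2), matrix(5, 2, 2), 1020, g)
  expect_true(all(complementary_gate(same) == 0))
})

test_that("dark/saturation correction linearizes counts", {
  g <- macro_gate()
  cfg <- small_config()
  F <- cfg$F

  zero <- count_image_pair(matrix(0, 8, 8), matrix(0, 8, 8), F, g)
  corr0 <- dark_saturation_correct(zero, dcr_map = 0, config = cfg)
  expect_true(all(corr0$g2 == 0) && all(corr0$int_ == 0))

  # counts/F = 0.01: correction inflates counts by < 1% (series of -log1p)
  k <- round(0.01 * F)
  low <- count_image_pair(matrix(0, 1, 1), matrix(k, 1, 1), F, g)
  corr <- dark_saturation_correct(low, dcr_map = 0, config = cfg)
  ratio <- corr$int_[1] / k
  expect_gte(ratio, 1.0)
  expect_lte(ratio, 1.01)

  # monotone in the input
  ks <- seq(0, F - 1, by = 51)
  vals <- vapply(ks, function(k) {
    p <- count_image_pair(matrix(0, 1, 1), matrix(k, 1, 1), F, g)
    dark_saturation_correct(p, dcr_map = 0, config = cfg)$int_[1]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  # saturating pixel: corrected ratio much closer to the analytic value
  cfgs <- sensor_config(shape = c(80L, 80L), bit_depth = 10)
  scene <- uniform_scene(0.8 * F, tau = 1.65, config = cfgs, gate = g)
  pair <- simulate_pair(scene, g, cfgs, seed = 10)
  R_true <- gate_ratio(1.65, g)
  raw_R <- mean(pair$g2) / mean(pair$int_)
  cp <- dark_saturation_correct(pair, dcr_map = 0, config = cfgs)
  corr_R <- mean(cp$g2) / mean(cp$int_)
  expect_lt(abs(corr_R - R_true), 0.5 * abs(raw_R - R_true))
})

test_that("lookup table is monotone, direction-aware and self-inverting", {
  lut_late <- build_lut(macro_gate())
  expect_identical(lut_late$direction, "increasing")
  lut_early <- build_lut(early_gate())
  expect_identical(lut_early$direction, "decreasing")

  # a slightly offset gate has a ratio that rises then falls towards W/T;
  # spanning the turnover must be rejected with a location
  expect_error(build_lut(gate_window(0.1, 3, 12.5),
                         tau_min = 0.01, tau_max = 100),
               "not strictly monotone")

  # round trip tau -> R -> tau over the working range, both gates
  taus <- exp(seq(log(0.25), log(5), length.out = 60))
  for (lut in list(lut_late, lut_early)) {
    back <- invert_ratio(gate_ratio(taus, lut$gate), lut)
    expect_lt(max(abs(back - taus) / taus), 1e-3)
  }

  # out-of-range ratios are masked, never clamped
  expect_true(is.na(invert_ratio(1.5, lut_late)))
  expect_true(is.na(invert_ratio(-0.1, lut_late)))
  expect_true(is.na(invert_ratio(0.999, lut_late)))  # above R(tau_max)

  # vectorized inversion preserves order per direction
  rr <- gate_ratio(taus, macro_gate())
  expect_true(all(diff(invert_ratio(rr, lut_late)) > 0))
})

test_that("estimate_map recovers lifetimes and masks low-count pixels", {
  g <- macro_gate()
  lut <- build_lut(g)
  cfg <- sensor_config(shape = c(10L, 10L), bit_depth = 10)

  # noiseless expected-value pair at tau = 1.65 -> uniform map
  scene <- uniform_scene(200, tau = 1.65, config = cfg, gate = g)
  nl <- simulate_pair(scene, g, cfg, noiseless = TRUE)
  map <- estimate_map(nl, lut, config = cfg, correct = TRUE)
  expect_true(all(map$valid))
  expect_lt(max(abs(map$tau - 1.65) / 1.65), 2e-3)

  # INT = 0 pixels are invalid without warnings
  empty <- count_image_pair(matrix(0L, 4, 4), matrix(0L, 4, 4), cfg$F, g)
  expect_no_warning(m0 <- estimate_map(empty, lut))
  expect_true(all(!m0$valid))
  expect_true(all(is.na(m0$tau)))
  expect_equal(sum(m0$valid) + m0$n_masked, 16)

  # scale invariance: scaling both channels leaves tau unchanged
  for (c_ in c(0.1, 10)) {
    scaled <- list(g2 = nl$g2 * c_, int_ = nl$int_ * c_, F = nl$F,
                   gate = g)
    ms <- estimate_map(scaled, lut, correct = FALSE)
    mr <- estimate_map(nl, lut, correct = FALSE)
    expect_equal(ms$tau, mr$tau, tolerance = 1e-12)
  }

  # gate mismatch is a configuration error
  expect_error(estimate_map(nl, build_lut(early_gate())), "different gate")

  # two-region scene separates cleanly at F = 1020, p ~ 0.3
  cfg2 <- sensor_config(shape = c(40L, 80L), bit_depth = 10)
  A0 <- uniform_scene(306, tau = 1, config = cfg2, gate = g)$A0
  tau_map <- cbind(matrix(1, 40, 40), matrix(1.65, 40, 40))
  sc2 <- scene_map(A0, tau_map)
  pr <- simulate_pair(sc2, g, cfg2, seed = 12)
  m2 <- estimate_map(pr, lut, config = cfg2, correct = TRUE)
  left <- as.numeric(m2$tau[, 1:40]); right <- as.numeric(m2$tau[, 41:80])
  se_pool <- sqrt(var(left, na.rm = TRUE) / sum(!is.na(left)) +
                    var(right, na.rm = TRUE) / sum(!is.na(right)))
  expect_gt((mean(right, na.rm = TRUE) - mean(left, na.rm = TRUE)) /
              se_pool, 5)
})

test_that("per-pixel offset maps shift the effective gate delay", {
  g <- macro_gate()
  lut <- build_lut(g)
  cfg <- sensor_config(shape = c(4L, 4L), bit_depth = 10)
  # scene whose decays start 0.5 ns late, as from a longer photon path;
  # amplitude set for a per-frame bit probability of ~0.2
  A0 <- -log(1 - 0.2) /
    (cfg$N * cfg$pde * 1.65 * (1 - exp(-(12.5 - 0.5) / 1.65)))
  scene <- scene_map(matrix(A0, 4, 4), tau = 1.65,
                     offset = matrix(0.5, 4, 4))
  nl <- simulate_pair(scene, g, cfg, noiseless = TRUE)

  plain <- estimate_map(nl, lut, config = cfg, correct = TRUE)
  shifted <- estimate_map(nl, lut, config = cfg, correct = TRUE,
                          offset_map = matrix(0.5, 4, 4))
  # without the offset correction the late decay biases tau upward
  expect_gt(abs(mean(plain$tau) - 1.65), 0.05)
  expect_lt(max(abs(shifted$tau - 1.65) / 1.65), 2e-3)
})

test_that("intensity weighting rescales by INT and zeroes invalid pixels", {
  g <- macro_gate()
  lut <- build_lut(g)
  tau <- matrix(c(1, 1.65, 2, NA), 2, 2)
  counts <- matrix(c(100, 50, 100, 0), 2, 2)
  map <- structure(list(tau = tau, valid = !is.na(tau), r = tau * 0,
                        counts_int = counts, n_masked = 1),
                   class = "lifetime_map")
  w <- intensity_weighted_map(map)
  expect_equal(w[1, 1], 1)         # full weight at max counts
  expect_equal(w[2, 1], 1.65 / 2)  # half weight
  expect_equal(w[2, 2], 0)         # invalid -> 0

  # uniform intensity: a rescaled copy, argmax preserved
  map$counts_int <- matrix(80, 2, 2)
  w2 <- intensity_weighted_map(map)
  expect_equal(w2[1:3], tau[1:3])
  expect_equal(which.max(w2[1:3]), which.max(tau[1:3]))
})

test_that("estimator precision follows square-root photon statistics", {
  g <- early_gate()  # the s = 0 lookup-table gate keeps G2 well populated
  cfg <- sensor_config(shape = c(1L, 1L), bit_depth = NA, F = 20000L)
  res <- precision_study(g, tau = 1, photon_budgets = c(100, 400, 1600),
                         n_repeats = 600, config = cfg, seed = 17)
  expect_equal(res$slope, -0.5, tolerance = 0.07)
  # quadrupling the budget halves the spread
  expect_equal(res$table$sd[1] / res$table$sd[2], 2, tolerance = 0.15)
  expect_equal(res$table$sd[2] / res$table$sd[3], 2, tolerance = 0.15)
  # bias shrinks with budget
  expect_lt(abs(res$table$bias[3]) / 1, 0.01)
})
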