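# Shared fixtures: the macroscopic acquisition geometry (80 MHz laser,
# 3 ns gate delayed 5.5 ns) and small sensor configs used across tests.

macro_gate <- function() gate_window(s = 5.5, W = 3, T = 12.5)
early_gate <- function() gate_window(s = 0, W = 3, T = 12.5)
int_gate <- function() gate_window(s = 0, W = 12.5, T = 12.5)

small_config <- function(...) {
  sensor_config(shape = c(8L, 8L), bit_depth = 10, ...)
}

# Uniform scene with expected detected INT photons per acquisition set to
# `budget` for the given lifetime and config (inverts the Bernoulli-frame
# saturation so the expectation is exact).
uniform_scene <- function(budget, tau, config, gate) {
  p_total <- budget / config$F
  stopifnot(p_total < 1)
  lam_t <- -log(1 - p_total) / config$N
  A0 <- lam_t / (config$pde * tau * (1 - exp(-gate$T / tau)))
  scene_map(matrix(A0, config$shape[1], config$shape[2]), tau)
}

# Independent trapezoid quadrature of f over [a, b] at fine resolution.
quad_trapz <- function(f, a, b, n = 20001) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (b - a) / (n - 1)
}
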