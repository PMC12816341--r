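# Shared fixtures: benchmark models with analytically known measures.

# Y1 white, Y2_n = Y1_{n-1} + U2: F_gc(1->2) = log 2, everything else 0.
unidir_model <- function(gain = 1) benchmark_unidirectional(gain)

# Uncoupled, unit-variance white pair.
white_model <- function() arx_model(list(matrix(0, 2, 2)), diag(2))

# Purely instantaneous coupling: no lagged terms, correlated innovations.
instant_model <- function(rho = 0.5)
  arx_model(list(matrix(0, 2, 2)), matrix(c(1, rho, rho, 1), 2, 2))

# Fixed bivariate AR(3) with substantial lag-3 dynamics, for order selection.
ar3_model <- function() {
  A1 <- matrix(c(0.40, 0.00, 0.15, 0.30), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.30, 0.00, 0.00, -0.25), 2, 2, byrow = TRUE)
  A3 <- matrix(c(0.30, 0.00, 0.20, 0.30), 2, 2, byrow = TRUE)
  arx_model(list(A1, A2, A3), diag(2))
}

sim_pair <- function(model, L, seed, ...) {
  simulate_arx(sim_spec(model, L = L, seed = seed, ...))
}

expect_all_near <- function(x, y, tol) {
  expect_true(max(abs(x - y)) < tol,
              label = sprintf("max abs deviation %.3g < %.3g",
                              max(abs(x - y)), tol))
}
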