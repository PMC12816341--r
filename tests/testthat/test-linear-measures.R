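test_that("pearson handles exact and stochastic linear dependence", {
  set.seed(21)
  y <- rnorm(500)
  expect_equal(pearson(ts_pair(y, 2 * y)), 1, tolerance = 1e-12)
  expect_equal(pearson(ts_pair(y, -y)), -1, tolerance = 1e-12)
  expect_error(pearson(ts_pair(rep(1, 60), rnorm(60))), "zero variance")

  rho <- 0.6
  n <- 1e5
  x <- rnorm(n)
  z <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_equal(pearson(ts_pair(x, z)), rho, tolerance = 0.01)
})

test_that("biased cross-correlation has the contract normalization and symmetry", {
  set.seed(8)
  y <- rnorm(400)
  pair <- ts_pair(y, y)
  cc <- cross_correlation(pair, 10)
  # lag 0 equals the biased sample variance, and is the maximum
  expect_equal(cc$R[cc$lag == 0], sum(y^2) / 400, tolerance = 1e-12)
  expect_true(all(cc$R[cc$lag == 0] >= abs(cc$R)))
  # R_12(-k) = R_21(k)
  x2 <- rnorm(400)
  p12 <- cross_correlation(ts_pair(y, x2), 5)
  p21 <- cross_correlation(ts_pair(x2, y), 5)
  expect_all_near(p12$R, rev(p21$R), 1e-12)
  expect_error(cross_correlation(pair, 400), "max_lag")
})

test_that("cross-correlation locates a pure delay", {
  set.seed(13)
  L <- 2000
  x <- rnorm(L + 3)
  y1 <- x[4:(L + 3)]
  y2 <- x[1:L]            # y2 delayed: y2_n = y1_{n-3}
  cc <- cross_correlation(ts_pair(y1, y2), 8)
  # R(k) = mean(y1_n y2_{n-k}) peaks where y1_n aligns with its copy: k = -3
  expect_identical(cc$lag[which.max(abs(cc$R))], -3L)

  wp <- ts_pair(rnorm(L), rnorm(L))
  w <- cross_correlation(wp, 10)
  norm0 <- sqrt(cross_correlation(wp, 0, "auto1")$R *
                  cross_correlation(wp, 0, "auto2")$R)
  expect_true(all(abs(w$R) / norm0 < 4 / sqrt(L)))
})

test_that("Gaussian mutual information closed form", {
  expect_identical(mi_gaussian(0), 0)
  expect_equal(mi_gaussian(0.6), -0.5 * log(1 - 0.36), tolerance = 1e-15)
  expect_identical(mi_gaussian(0.6), mi_gaussian(-0.6))
  expect_error(mi_gaussian(1), "degenerate")
})

test_that("time-domain measures reproduce closed-form benchmarks", {
  # uncoupled: everything zero
  m0 <- arx_model(list(diag(c(0.5, 0.3))), diag(2))
  td0 <- time_domain_measures(m0, restrict_ss(m0, 1L), restrict_ss(m0, 2L))
  expect_all_near(unlist(td0[c("F_td", "F_gc_12", "F_gc_21", "F_ic")]), 0,
                  1e-8)

  # unidirectional benchmark: F_gc_12 = log 2, T_12 = log(2)/2
  m <- unidir_model()
  td <- time_domain_measures(m, restrict_ss(m, 1L), restrict_ss(m, 2L))
  expect_equal(td$F_gc_12, log(2), tolerance = 1e-6)
  expect_equal(td$T_12, log(2) / 2, tolerance = 1e-6)
  expect_lt(abs(td$F_gc_21), 1e-8)
  expect_lt(abs(td$F_ic), 1e-8)

  # purely instantaneous: F_ic = log(1/0.75), GCs zero
  mi <- instant_model(0.5)
  tdi <- time_domain_measures(mi, restrict_ss(mi, 1L), restrict_ss(mi, 2L))
  expect_equal(tdi$F_ic, log(1 / 0.75), tolerance = 1e-8)
  expect_lt(abs(tdi$F_gc_12), 1e-8)
  expect_lt(abs(tdi$F_gc_21), 1e-8)
})

test_that("decomposition, halving and entropy-rate identity hold exactly", {
  set.seed(77)
  for (i in 1:20) {
    m <- random_stable_model(p = 2, strictly_causal = FALSE)
    r1 <- restrict_ss(m, 1L)
    r2 <- restrict_ss(m, 2L)
    td <- time_domain_measures(m, r1, r2, clip_negative = FALSE)
    expect_lt(abs(td$F_td - (td$F_gc_12 + td$F_gc_21 + td$F_ic)), 1e-8)
    expect_identical(td$I_mir, td$F_td / 2)
    expect_identical(td$T_12, td$F_gc_12 / 2)
    # Gaussian entropy-rate identity: MIR = sum of entropy-rate differences
    mir_h <- 0.5 * log(r1$lambda2) + 0.5 * log(r2$lambda2) -
      0.5 * log(det(m$Sigma_U))
    expect_lt(abs(td$I_mir - mir_h), 1e-12)
    expect_gt(td$F_td, -1e-10)  # population non-negativity
  }
})

test_that("estimated measures converge to population values", {
  model <- benchmark_physio(c12 = 0.6, c21 = 0.2)$model
  pop <- population_measures(model, n_freq = 257)
  errs <- sapply(1:10, function(s) {
    pair <- sim_pair(model, L = 20000, seed = 100 + s)
    est <- linear_measures(pair, p = 2)
    abs(c(est$T_12 - pop$time$T_12, est$T_21 - pop$time$T_21,
          est$I_it - pop$time$I_it))
  })
  expect_lt(max(rowMeans(errs)), 0.02)
})
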