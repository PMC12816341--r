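test_that("white noise has a flat identity PSD", {
  spec <- transfer_and_psd(white_model(), n_freq = 101)
  expect_all_near(Re(spec$P[1, 1, ]), 1, 1e-12)
  expect_all_near(Re(spec$P[2, 2, ]), 1, 1e-12)
  expect_all_near(Mod(spec$P[1, 2, ]), 0, 1e-12)
  expect_error(transfer_and_psd(white_model(), n_freq = 32), "at least 64")
})

test_that("AR(1) spectrum matches the closed form at f = 0", {
  m <- arx_model(list(diag(c(0.5, 0))), diag(2))
  spec <- transfer_and_psd(m, n_freq = 101)
  expect_equal(Re(spec$P[1, 1, 1]), 1 / (1 - 0.5)^2, tolerance = 1e-12)
})

test_that("unidirectional benchmark has flat coh2 = dc2 = 0.5 and f_gc = log 2", {
  spec <- spectral_measures(unidir_model(), n_freq = 257)
  expect_all_near(spec$coh2, 0.5, 1e-10)
  expect_all_near(spec$f_td, log(2), 1e-10)
  expect_all_near(spec$dc2_12, 0.5, 1e-10)
  expect_all_near(spec$dc2_21, 0, 1e-10)
  expect_all_near(spec$f_gc_12, log(2), 1e-10)
  expect_all_near(spec$f_gc_21, 0, 1e-10)
  expect_all_near(spec$f_ic, 0, 1e-10)
  # P22 = 2 flat
  expect_all_near(Re(spec$P[2, 2, ]), 2, 1e-12)
})

test_that("spectral identities hold on random models", {
  set.seed(31)
  for (i in 1:15) {
    strict <- i %% 2 == 0
    m <- random_stable_model(p = 2, strictly_causal = strict)
    spec <- spectral_measures(m, n_freq = 129, warn_nondiagonal = FALSE)
    # frequency-wise Geweke decomposition
    expect_all_near(spec$f_td,
                    spec$f_gc_12 + spec$f_gc_21 + spec$f_ic, 1e-10)
    # f_td = -log(1 - coh2)
    expect_all_near(spec$f_td, -log(1 - spec$coh2), 1e-8)
    expect_true(all(spec$coh2 >= 0 & spec$coh2 <= 1))
    if (strict) {
      # DC rows normalize to 1 and f_gc = -log(1 - dc2)
      s1 <- m$Sigma_U[1, 1]; s2 <- m$Sigma_U[2, 2]
      row2 <- s1 * Mod(spec$H[2, 1, ])^2 + s2 * Mod(spec$H[2, 2, ])^2
      dc_iso2 <- s2 * Mod(spec$H[2, 2, ])^2 / row2
      expect_all_near(spec$dc2_12 + dc_iso2, 1, 1e-10)
      expect_all_near(spec$f_gc_12, -log(1 - spec$dc2_12), 1e-10)
    }
  }
})

test_that("coherence is symmetric in process exchange, DC is not", {
  m <- benchmark_physio(c12 = 0.7, c21 = 0)$model
  sw <- arx_model(lapply(m$A, function(a) a[2:1, 2:1]),
                  m$Sigma_U[2:1, 2:1])  # swap process labels
  s1 <- spectral_measures(m, n_freq = 129)
  s2 <- spectral_measures(sw, n_freq = 129)
  expect_all_near(s1$coh2, s2$coh2, 1e-10)
  expect_all_near(s1$dc2_12, s2$dc2_21, 1e-10)
  expect_gt(max(s1$dc2_12), 0.1)
  expect_all_near(s1$dc2_21, 0, 1e-10)
})

test_that("band integration is additive and matches time-domain measures", {
  m <- benchmark_physio(c12 = 0.6, c21 = 0.3,
                        Sigma_U = matrix(c(1, .3, .3, 1), 2, 2))$model
  spec <- spectral_measures(m, n_freq = 1001, warn_nondiagonal = FALSE)
  whole <- band_integrate(spec, "f_td")
  parts <- band_integrate(spec, "f_td", c(0, 0.04)) +
    band_integrate(spec, "f_td", c(0.04, 0.15)) +
    band_integrate(spec, "f_td", c(0.15, 0.40)) +
    band_integrate(spec, "f_td", c(0.40, 0.50))
  expect_lt(abs(whole - parts), 1e-9)
  # off-grid edges still partition exactly
  odd <- band_integrate(spec, "f_td", c(0, 0.1234567)) +
    band_integrate(spec, "f_td", c(0.1234567, 0.5))
  expect_lt(abs(whole - odd), 1e-9)

  td <- time_domain_measures(m, restrict_ss(m, 1L), restrict_ss(m, 2L),
                             clip_negative = FALSE)
  expect_lt(abs(td$I_mir - whole), 1e-3)
  expect_lt(abs(td$T_12 - band_integrate(spec, "f_gc_12")), 1e-3)
  expect_error(band_integrate(spec, "f_td", c(0.6, 0.7)), "empty band")
})

test_that("unidirectional benchmark integrates to T = log(2)/2 over the whole band", {
  spec <- spectral_measures(unidir_model(), n_freq = 513)
  expect_equal(band_integrate(spec, "f_gc_12"), log(2) / 2, tolerance = 1e-6)
  expect_identical(band_integrate(spec, rep(0, 513)), 0)
})

test_that("Parzen window and truncation-lag relation", {
  expect_identical(parzen_window(0, 10), 1)
  expect_equal(parzen_window(10, 10), 0, tolerance = 1e-15)
  expect_equal(parzen_window(5, 10), 1 - 6 * 0.25 + 6 * 0.125,
               tolerance = 1e-15)
  expect_equal(parzen_window(8, 10), 2 * (1 - 0.8)^3, tolerance = 1e-15)

  expect_equal(parzen_truncation_lag(1.273, 1)$tau_raw, 1, tolerance = 1e-12)
  pt <- parzen_truncation_lag(0.1, 1)
  expect_equal(pt$tau_raw, 12.73, tolerance = 1e-12)
  expect_identical(pt$tau, 13L)
  expect_error(parzen_truncation_lag(0), "positive")
})

test_that("weighted-covariance PSD: variance identity and white flatness", {
  set.seed(19)
  pair <- preprocess(ts_pair(rnorm(4096), rnorm(4096)))
  spec <- wc_psd(pair, truncation_lag = 40, n_freq = 401)
  # two-sided integral of the autospectrum equals the biased sample variance
  P11 <- Re(spec$P[1, 1, ])
  int2 <- 2 * sum(diff(spec$f_norm) * (head(P11, -1) + tail(P11, -1)) / 2)
  expect_lt(abs(int2 - sum(pair$y1^2) / pair$L), 1e-8)
  expect_true(all(P11 > -1e-12))
  # flat around 1 within a Monte-Carlo envelope (var ~ P^2 * 0.75 tau / L)
  se <- sqrt(0.75 * 40 / 4096)
  expect_all_near(P11, 1, 5 * se)
  expect_error(wc_psd(pair, 0), "truncation_lag")
})

test_that("weighted-covariance PSD locates an AR(2) spectral peak", {
  f0 <- 0.1
  m <- arx_model(list(diag(c(2 * 0.9 * cos(2 * pi * f0), 0)),
                      diag(c(-0.81, 0))), diag(2))
  pair <- sim_pair(m, L = 8192, seed = 23)
  spec <- wc_psd(pair, truncation_lag = 60, n_freq = 801)
  fhat <- spec$f_norm[which.max(Re(spec$P[1, 1, ]))]
  # oracle: the parametric spectrum of the generating model
  pspec <- transfer_and_psd(m, n_freq = 801)
  fpar <- pspec$f_norm[which.max(Re(pspec$P[1, 1, ]))]
  expect_lt(abs(fhat - fpar), 0.02)
  expect_lt(abs(fhat - f0), 0.02)
})

test_that("spectral_table exports all computed profiles", {
  spec <- spectral_measures(unidir_model(), n_freq = 65)
  df <- spectral_table(spec)
  expect_true(all(c("f_norm", "f_hz", "P11", "P22", "ReP12", "ImP12",
                    "coh2", "dc2_12", "dc2_21", "f_td", "f_gc_12",
                    "f_gc_21", "f_ic") %in% names(df)))
  expect_identical(nrow(df), 65L)
})
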