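test_that("uniform embedding has the contract geometry", {
  pair <- ts_pair(1:60, 61:120, min_length = 10)
  emb <- build_embedding_uniform(pair, q = 2, tau = 1)
  expect_identical(emb$N, 58L)
  # lags 3, 6, 9 for q = 3, tau = 3
  emb2 <- build_embedding_uniform(pair, q = 3, tau = 3)
  expect_identical(emb2$lags, c(3L, 6L, 9L) * 1L)
  # past column at lag d equals the present column of the delayed series
  expect_identical(emb2$Y1q[, 2], pair$y1[(10:60) - 6])
  expect_error(build_embedding_uniform(ts_pair(1:60, 1:60, min_length = 10),
                                       q = 30, tau = 2), "too short")
})

test_that("quantize applies the half-open binning rule", {
  x <- c(0, 0.4, 0.6, 1)
  expect_identical(quantize(x, 2), c(1L, 1L, 2L, 2L))
  expect_identical(quantize(x, 4)[4], 4L)  # maximum goes to the top bin
  expect_error(quantize(rep(2, 10), 3), "constant")
  # uniform sample approaches the equiprobable-alphabet entropy log(4)
  set.seed(4)
  s <- quantize(runif(20000), 4)
  p <- table(s) / length(s)
  expect_equal(-sum(p * log(p)), log(4), tolerance = 0.01)
})

test_that("rank patterns follow the later-gets-smaller-rank tie rule", {
  expect_identical(rank_pattern(c(3.1, 1.2, 2.5)), c(3L, 1L, 2L))
  expect_identical(rank_pattern(c(5, 5)), c(2L, 1L))
  expect_identical(rank_pattern(1:5), 1:5)
  # i.i.d. data, q = 2: two equiprobable patterns -> log 2 nats
  set.seed(14)
  M <- matrix(runif(2 * 20000), ncol = 2)
  pats <- t(apply(M, 1, rank_pattern))
  p <- table(paste(pats[, 1], pats[, 2])) / nrow(pats)
  expect_equal(-sum(p * log(p)), log(2), tolerance = 1e-3)
})

test_that("binning recovers the exact discrete benchmark", {
  set.seed(25)
  L <- 6000
  y1 <- runif(L)
  y2 <- c(y1[L], y1[-L])  # y2_n = y1_{n-1}
  mf <- binning_measures(ts_pair(y1, y2), q = 1, tau = 1, b = 2, warn = FALSE)
  expect_equal(mf$T_12, log(2), tolerance = 0.02)
  expect_lt(abs(mf$T_21), 0.02)
  expect_identical(mf$I_mir, mf$T_12 + mf$T_21 + mf$I_it)

  # independent pre-discretized series: everything near zero
  i1 <- as.numeric(sample(0:1, L, replace = TRUE))
  i2 <- as.numeric(sample(0:1, L, replace = TRUE))
  mf0 <- binning_measures(ts_pair(i1, i2), q = 1, tau = 1, b = 2,
                          warn = FALSE)
  expect_all_near(unlist(mf0[c("T_12", "T_21", "I_it")]), 0, 0.01)

  # the climate-analysis setting b = 3, q = 2 passes the alphabet rule at 792
  pair <- sim_pair(white_model(), L = 792, seed = 2)
  expect_silent(binning_measures(pair, q = 2, tau = 1, b = 3))
  expect_warning(binning_measures(pair, q = 4, tau = 1, b = 5),
                 "alphabet")
})

test_that("permutation estimator separates coupled from uncoupled pairs", {
  coupled <- benchmark_physio(c12 = 1.2, c21 = 0)
  t_coup <- sapply(1:8, function(s)
    permutation_measures(sim_pair(coupled$model, 1000, s), q = 3)$T_12)
  t_unc <- sapply(1:20, function(s)
    permutation_measures(sim_pair(white_model(), 1000, 100 + s), q = 3)$T_12)
  expect_gt(mean(t_coup), quantile(t_unc, 0.95))

  # decomposition holds exactly by construction
  mf <- permutation_measures(sim_pair(coupled$model, 800, 3), q = 3)
  expect_identical(mf$I_mir, mf$T_12 + mf$T_21 + mf$I_it)
})

test_that("permutation measures are invariant under monotone transforms", {
  pair <- sim_pair(benchmark_physio(c12 = 0.8)$model, 600, 11)
  a <- permutation_measures(pair, q = 3)
  mono <- ts_pair(exp(pair$y1), pair$y2^3, min_length = 50)
  b <- permutation_measures(mono, q = 3)
  expect_all_near(unlist(a[c("T_12", "T_21", "I_it")]),
                  unlist(b[c("T_12", "T_21", "I_it")]), 1e-12)
})

test_that("binning is invariant under per-series affine maps, knn under common ones", {
  pair <- sim_pair(benchmark_physio(c12 = 0.8)$model, 600, 12)
  aff <- ts_pair(3 * pair$y1 - 7, -2 * pair$y2 + 1, min_length = 50)
  b0 <- binning_measures(pair, q = 2, b = 3, warn = FALSE)
  b1 <- binning_measures(aff, q = 2, b = 3, warn = FALSE)
  # a sign flip reverses bin order but not the partition: entropies identical
  expect_all_near(unlist(b0[c("T_12", "T_21", "I_it")]),
                  unlist(b1[c("T_12", "T_21", "I_it")]), 1e-12)

  k0 <- knn_measures(pair, q = 1, k = 5)
  common <- ts_pair(2.5 * pair$y1 + 1, 2.5 * pair$y2 + 1, min_length = 50)
  k1 <- knn_measures(common, q = 1, k = 5)
  expect_all_near(unlist(k0[c("T_12", "T_21", "I_it")]),
                  unlist(k1[c("T_12", "T_21", "I_it")]), 1e-10)
})

test_that("knn estimator is near zero for independent series", {
  vals <- sapply(1:5, function(s) {
    pair <- sim_pair(white_model(), 2048, 300 + s)
    mf <- knn_measures(pair, q = 3, tau = 1, k = 10)
    c(mf$T_12, mf$T_21, mf$I_it)
  })
  expect_all_near(rowMeans(vals), 0, 0.02)
})

test_that("knn estimator matches the linear oracle on a Gaussian benchmark", {
  vals <- sapply(1:5, function(s) {
    pair <- sim_pair(unidir_model(), 4096, 40 + s)
    mf <- knn_measures(pair, q = 1, tau = 1, k = 10)
    c(mf$T_12, mf$T_21)
  })
  expect_lt(abs(mean(vals[1, ]) - log(2) / 2), 0.03)
  expect_lt(abs(mean(vals[2, ])), 0.02)
})

test_that("knn entropy matches the Gaussian closed form and guards input", {
  set.seed(55)
  expect_equal(knn_entropy(rnorm(10000), k = 10), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.02)
  expect_error(knn_entropy(rnorm(5), k = 10), "smaller")
  expect_error(knn_entropy(rep(c(1, 2), 50), k = 3), "duplicate")
  # jitter breaks ties deterministically
  p <- ts_pair(rep(c(1, 2, 3), 40), rep(c(4, 5), 60), min_length = 50)
  m1 <- knn_measures(p, q = 1, k = 4, jitter = TRUE, jitter_seed = 9)
  m2 <- knn_measures(p, q = 1, k = 4, jitter = TRUE, jitter_seed = 9)
  expect_identical(m1$I_mir, m2$I_mir)
})

test_that("seeded model-free runs are bit-reproducible", {
  pair <- sim_pair(unidir_model(), 1024, 77)
  expect_identical(knn_measures(pair, q = 2, k = 10)$I_mir,
                   knn_measures(pair, q = 2, k = 10)$I_mir)
  expect_identical(binning_measures(pair, b = 3)$I_mir,
                   binning_measures(pair, b = 3)$I_mir)
})

test_that("non-uniform embedding selects the true coupling lag", {
  hits <- sapply(1:10, function(s) {
    set.seed(900 + s)
    L <- 600
    y1 <- rnorm(L)
    y2 <- c(rnorm(2), y1[1:(L - 2)]) + rnorm(L, sd = 0.3)
    spec <- select_embedding_nonuniform(ts_pair(y1, y2), target = 2L,
                                        q_max = 3, tau = 1,
                                        n_shuffles = 60, seed = s)
    nrow(spec$candidates) >= 1 &&
      spec$candidates$process[1] == 1 && spec$candidates$lag[1] == 2
  })
  expect_gte(mean(hits), 0.9)

  # white-noise target: nothing significant, empty spec is valid
  wn <- sim_pair(white_model(), 400, 5)
  spec0 <- select_embedding_nonuniform(wn, target = 2L, q_max = 2,
                                       n_shuffles = 60, seed = 3)
  expect_lte(nrow(spec0$candidates), 1)
})
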