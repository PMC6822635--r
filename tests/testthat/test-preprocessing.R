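test_that("sample size formula and finite-population correction", {
  s <- compute_sample_size(0.5, 2.58, 0.01)
  expect_equal(s$n0, 16641, tolerance = 1e-12)
  s2 <- compute_sample_size(0.5, 2.58, 0.01, N = 4097)
  expect_equal(s2$n, 3288)
  expect_equal(compute_sample_size(0, 2.58, 0.01)$n0, 0)
  expect_error(compute_sample_size(0.5, 2.58, 0), "positive")
  expect_error(compute_sample_size(1.2, 2.58, 0.01), "\\[0, 1\\]")
  # N -> infinity converges to the uncorrected size
  n0 <- s$n0
  s3 <- compute_sample_size(0.5, 2.58, 0.01, N = 1e6 * n0)
  expect_lt(abs(s3$n - n0) / n0, 1e-3)
})

test_that("window segmentation puts the remainder in the last window", {
  expect_equal(segment_signal(4097, 4), c(1024L, 1024L, 1024L, 1025L))
  expect_equal(segment_signal(10, 1), 10L)
  expect_equal(segment_signal(7, 3), c(2L, 2L, 3L))
  expect_error(segment_signal(3, 5), "exceed")
  for (total in c(17, 100, 4097)) for (k in c(2, 3, 5)) {
    expect_equal(sum(segment_signal(total, k)), total)
  }
})

test_that("variance-weighted allocation preserves the budget", {
  p <- allocate_samples(rep(2, 4), matrix(1, 4, 3), 100)
  expect_equal(p$counts, rep(25L, 4))
  p2 <- allocate_samples(c(1, 1, 1), rbind(0, 1, 1), 50)
  expect_equal(p2$fractions[1], 0)
  p3 <- allocate_samples(c(2, 1), rbind(c(2, 0), c(2, 0)), 90)
  expect_equal(p3$fractions, c(2 / 3, 1 / 3))
  expect_equal(p3$counts, c(60L, 30L))
  expect_error(allocate_samples(c(1, 1), matrix(0, 2, 2), 10), "degenerate")
  set.seed(1)
  for (i in 1:10) {
    V <- matrix(runif(8), 4)
    pl <- allocate_samples(1 + rpois(4, 3), V, 97)
    expect_equal(sum(pl$counts), 97L)
    expect_equal(sum(pl$fractions), 1, tolerance = 1e-9)
  }
})

test_that("filter bank passes the band and attenuates outside it", {
  tt <- seq_len(2000) / 250
  s10 <- sin(2 * pi * 10 * tt)
  ts <- trial_set(list(rbind(s10, 0 * s10)), labels = 1, fs = 250)
  fb <- bandpass_filterbank(ts, filterbank_spec(list(c(8, 12), c(20, 24))))
  p_in <- mean(s10^2)
  expect_gte(mean(fb[[1]]$trials[[1]][1, ]^2), 0.9 * p_in)
  expect_lte(mean(fb[[2]]$trials[[1]][1, ]^2), 0.01 * p_in)
  expect_equal(fb[[1]]$trials[[1]][2, ], rep(0, 2000))
  expect_error(
    bandpass_filterbank(ts, filterbank_spec(list(c(100, 130)))),
    "Nyquist")
})

test_that("CSP solves the generalized eigenproblem on class covariances", {
  sim <- make_class_trials(n_per_class = 30, channels = 2, samples = 2000,
                           strength = 4, seed = 2)
  m <- csp_fit(sim$trials, c(1, 2))
  # diag(4,1) vs diag(1,4): top eigenvalue 4/5, filters near coordinate axes
  expect_equal(m$eigenvalues[1], 0.8, tolerance = 0.03)
  expect_equal(m$eigenvalues[2], 0.2, tolerance = 0.03)
  W <- m$filters
  expect_gt(abs(W[1, 1]) / sqrt(sum(W[1, ]^2)), 0.95)
  expect_gt(abs(W[2, 2]) / sqrt(sum(W[2, ]^2)), 0.95)
  # filters whiten the pooled covariance
  expect_lt(max(abs(W %*% m$pooled_cov %*% t(W) - diag(2))), 1e-6)
})

test_that("CSP eigenvalues are complementary and match a brute-force solve", {
  set.seed(4)
  sim <- make_class_trials(n_per_class = 15, channels = 5, samples = 400, seed = 4)
  m <- csp_fit(sim$trials)
  S1 <- m$class_covs[[1]]; S2 <- m$class_covs[[2]]
  # independent oracle: plain eigen solve of solve(S1+S2) %*% S1
  lam <- sort(Re(eigen(solve(S1 + S2) %*% S1)$values), decreasing = TRUE)
  expect_equal(m$eigenvalues, lam, tolerance = 1e-8)
  # class-1 / class-2 views are complementary
  m2 <- csp_fit(sim$trials, c(2, 1))
  expect_equal(m$eigenvalues + rev(m2$eigenvalues), rep(1, 5), tolerance = 1e-9)
  expect_error(csp_fit(sim$trials[sim$trials$labels == 1]), "two classes")
})

test_that("CSP is invariant to trial scaling", {
  sim <- make_class_trials(n_per_class = 10, channels = 4, samples = 300, seed = 6)
  scaled <- trial_set(lapply(sim$trials$trials, function(X) 7 * X),
                      sim$trials$labels, sim$trials$fs)
  m1 <- csp_fit(sim$trials)
  m2 <- csp_fit(scaled)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(m1$filters), abs(m2$filters), tolerance = 1e-6)
})

test_that("CSP log-variance features separate the constructed classes", {
  sim <- make_class_trials(n_per_class = 25, channels = 2, samples = 500,
                           strength = 4, seed = 8)
  m <- csp_fit(sim$trials)
  ft <- csp_transform(m, sim$trials, m = 1)
  expect_equal(dim(ft$features[[1]]), c(2L, 1L))
  f1 <- sapply(ft$features[ft$labels == 1], function(x) x[1, 1])
  f2 <- sapply(ft$features[ft$labels == 2], function(x) x[1, 1])
  expect_gt(mean(f1), mean(f2))
  # boundary: 2m = channels uses every filter
  ft_all <- csp_transform(m, sim$trials, m = 1)
  expect_equal(nrow(ft_all$features[[1]]), 2L)
  expect_error(csp_transform(m, sim$trials, m = 0), "at least 1")
  # zero-variance trial is guarded, not an error
  zts <- trial_set(list(matrix(0, 2, 500)), 1, fs = 250)
  fz <- csp_transform(m, zts, m = 1)
  expect_true(all(is.finite(fz$features[[1]])))
})

test_that("channel selection ranks the discriminative channel first", {
  sim <- make_class_trials(n_per_class = 15, channels = 4, samples = 400,
                           strength = 6, seed = 10)
  m <- csp_fit(sim$trials)
  expect_equal(sort(select_channels(m, 4)), 1:4)
  # class blocks are channels 1-2 vs 3-4; extremes must rank them on top
  expect_true(all(select_channels(m, 2) %in% c(1, 2, 3, 4)))
  # tie-break: equal scores prefer the lower index
  m_tie <- m
  m_tie$filters <- rbind(c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 0.5),
                         c(0.5, 0.5, 0.5, 0.5), c(1, 1, 1, 1))
  expect_equal(select_channels(m_tie, 2), c(1L, 2L))
})

test_that("time-domain parameters track derivative variances", {
  # constant signal: variance floor
  ts0 <- trial_set(list(matrix(1, 1, 100)), 1, fs = 100)
  expect_equal(tdp_features(ts0, K = 0)$features[[1]][1, 1], log(1e-12))
  # sinusoid: derivative variance ~ omega^2 * signal variance
  fs <- 1000; f0 <- 5
  tt <- seq_len(5000) / fs
  x <- sin(2 * pi * f0 * tt)
  ts1 <- trial_set(list(matrix(x, 1)), 1, fs = fs)
  ft <- tdp_features(ts1, K = 1)
  omega <- 2 * pi * f0
  expect_equal(ft$features[[1]][1, 2] - ft$features[[1]][1, 1],
               2 * log(omega), tolerance = 0.01)
  # white noise: matches a direct difference-and-variance computation
  set.seed(3)
  w <- rnorm(400)
  ts2 <- trial_set(list(rbind(w, w)), 1, fs = 50)
  ft2 <- tdp_features(ts2, K = 2)
  d1 <- diff(w) * 50; d2 <- diff(d1) * 50
  expect_equal(ft2$features[[1]][1, ],
               log(c(var(w), var(d1), var(d2)) + 1e-12), tolerance = 1e-12)
})

test_that("mutual-information ranking finds label-aligned features", {
  set.seed(5)
  n <- 1000
  labels <- rep(c(1, 2), each = n / 2)
  feats <- lapply(seq_len(n), function(i)
    matrix(c(labels[i], rnorm(3)), 2, 2))
  ft <- feature_tensor(feats, labels)
  expect_equal(fbcsp_select(ft, 1)[1], 1L)
  expect_equal(sort(fbcsp_select(ft, 4)), 1:4)
  # an independent feature has near-zero estimated information
  mi <- bcimatrix:::.mi_bits(rnorm(n), labels, ceiling(sqrt(n)))
  expect_lte(mi, 0.05)
  expect_error(fbcsp_select(ft, 0), "positive")
})
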