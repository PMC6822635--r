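test_that("linear SVM baseline separates separable matrix data", {
  ft <- make_sep_features(seed = 1)
  m <- svm_baseline_fit(ft, C = 1)
  expect_equal(mean(smm_predict(m, ft) == ft$labels), 1)
  expect_error(svm_baseline_fit(ft[ft$labels == 1]), "two classes")
  expect_error(svm_baseline_fit(ft, C = 0), "positive")
  # duplicating every sample leaves the max-margin decision function unchanged
  ftw <- make_sep_features(gap = 3, seed = 1)
  mw <- svm_baseline_fit(ftw, C = 1)
  ft2 <- feature_tensor(c(ftw$features, ftw$features), c(ftw$labels, ftw$labels))
  m2 <- svm_baseline_fit(ft2, C = 1)
  expect_equal(smm_decision(m2, ftw), smm_decision(mw, ftw), tolerance = 1e-6)
})

test_that("SVM baseline objective matches an independent reference solver", {
  skip_if_not_installed("e1071")
  set.seed(2)
  n <- 40
  feats <- lapply(seq_len(n), function(i)
    matrix(rnorm(6, mean = ifelse(i <= n / 2, 0.5, -0.5)), 2, 3))
  ft <- feature_tensor(feats, rep(c(1, 2), each = n / 2))
  C <- 1
  m <- svm_baseline_fit(ft, C = C)
  Xv <- flatten_features(ft)
  ref <- e1071::svm(Xv, factor(ft$labels), kernel = "linear", cost = C, scale = FALSE)
  w <- crossprod(ref$SV, ref$coefs)
  y <- ifelse(ft$labels == 1, 1, -1)
  obj_ref <- 0.5 * sum(w^2) + C * hinge_sum(y * (Xv %*% w - ref$rho))
  expect_equal(m$solver_trace[1], obj_ref, tolerance = 1e-3)
})

test_that("robust SMM with zero penalties matches the SVM baseline in sign", {
  ft <- make_sep_features(n_per_class = 30, gap = 1.5, seed = 3)
  msvm <- svm_baseline_fit(ft, C = 1)
  m0 <- rsmm_fit_binary(ft, gamma = 0, tau = 0, C = 1)
  agree <- mean(sign(smm_decision(msvm, ft)[, 1]) == sign(smm_decision(m0, ft)[, 1]))
  expect_gte(agree, 0.99)
})

test_that("a dominant nuclear penalty collapses W to rank one", {
  ft <- make_sep_features(seed = 4)
  m <- rsmm_fit_binary(ft, gamma = 0, tau = 50, C = 1)
  expect_lte(bcimatrix:::.num_rank(m$W_lowrank[[1]]), 1)
})

test_that("robust SMM separates rank-1 discriminative structure", {
  set.seed(5)
  u <- c(1, -1) / sqrt(2); v <- c(1, 0, 1) / sqrt(2)
  feats <- lapply(1:40, function(i) {
    s <- if (i <= 20) 1 else -1
    s * 1.5 * u %*% t(v) + matrix(rnorm(6, sd = 0.2), 2, 3)
  })
  ft <- feature_tensor(feats, rep(c(1, 2), each = 20))
  m <- rsmm_fit_binary(ft, gamma = 0.05, tau = 0.5, C = 1)
  expect_equal(mean(smm_predict(m, ft) == ft$labels), 1)
  expect_lte(bcimatrix:::.num_rank(m$W_lowrank[[1]], rel_tol = 1e-6), 2)
})

test_that("ADMM incumbent objective is monotone after burn-in", {
  ft <- make_sep_features(seed = 6)
  m <- rsmm_fit_binary(ft, gamma = 0.1, tau = 0.1, C = 1)
  tr <- m$solver_trace
  expect_gt(length(tr), 5)
  post <- tr[-(1:5)]
  expect_true(all(diff(post) <= 1e-6 * pmax(1, abs(post[-length(post)]))))
})

test_that("decision function is invariant to a constant trial offset", {
  ft <- make_sep_features(n_per_class = 20, seed = 7)
  shift <- matrix(3, 2, 3)
  ft_shift <- feature_tensor(lapply(ft$features, function(X) X + shift), ft$labels)
  m1 <- rsmm_fit_binary(ft, gamma = 0.1, tau = 0.1, C = 1)
  m2 <- rsmm_fit_binary(ft_shift, gamma = 0.1, tau = 0.1, C = 1)
  d1 <- smm_decision(m1, ft)[, 1]
  d2 <- smm_decision(m2, ft_shift)[, 1]
  expect_equal(d2, d1, tolerance = 1e-4)
  expect_identical(smm_predict(m2, ft_shift), smm_predict(m1, ft))
})

test_that("an overwhelming row penalty empties W and freezes the prediction", {
  # unbalanced classes: the offset carries the majority-margin solution
  set.seed(8)
  feats <- lapply(1:55, function(i)
    matrix(rnorm(6, mean = ifelse(i <= 40, 0.8, -0.8)), 2, 3))
  ft <- feature_tensor(feats, c(rep(1, 40), rep(2, 15)))
  m <- rsmm_fit_binary(ft, gamma = 1e6, tau = 0, C = 1)
  expect_lt(max(abs(m$W[[1]])), 1e-4)
  pred <- smm_predict(m, ft)
  expect_equal(length(unique(pred)), 1L)
  expect_equal(unique(pred), 1)
})

test_that("multiclass one-vs-rest reduces, separates, and is label-order invariant", {
  ft2 <- make_sep_features(seed = 9)
  mb <- rsmm_fit_binary(ft2, gamma = 0.1, tau = 0.1, C = 1)
  mm <- rsmm_fit_multiclass(ft2, gamma = 0.1, tau = 0.1, C = 1)
  expect_equal(mm$W, mb$W)
  expect_equal(mm$b, mb$b)

  set.seed(9)
  centers <- list(c(3, 0), c(-3, 0), c(0, 3), c(0, -3))
  feats <- list(); labels <- integer(0)
  for (k in 1:4) for (i in 1:12) {
    feats <- c(feats, list(matrix(c(centers[[k]], 0, 0) + rnorm(4, sd = 0.4), 2, 2)))
    labels <- c(labels, k)
  }
  ft4 <- feature_tensor(feats, labels)
  m4 <- rsmm_fit_multiclass(ft4, gamma = 0.1, tau = 0.1, C = 1)
  expect_gte(mean(smm_predict(m4, ft4) == labels), 0.95)
  # permuting presentation order leaves predictions unchanged
  perm <- sample(length(labels))
  m4p <- rsmm_fit_multiclass(ft4[perm], gamma = 0.1, tau = 0.1, C = 1)
  expect_identical(smm_predict(m4p, ft4), smm_predict(m4, ft4))
})

test_that("prediction is the argmax decision with lowest-label tie-break", {
  ft <- make_sep_features(seed = 10)
  m <- rsmm_fit_binary(ft, gamma = 0.1, tau = 0.1, C = 1)
  dec <- smm_decision(m, ft)
  brute <- m$classes[max.col(dec, ties.method = "first")]
  expect_identical(smm_predict(m, ft), brute)
  # constructed exact tie: binary model decisions are +/- the same value
  tie <- m
  tie$W <- list(matrix(0, 2, 3), matrix(0, 2, 3))
  tie$b <- c(0.5, 0.5)
  class(tie) <- "smm_model"
  expect_equal(unique(smm_predict(tie, ft)), m$classes[1])
  expect_error(smm_predict(m, feature_tensor(list(matrix(0, 3, 3)), 1)), "shape")
})
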