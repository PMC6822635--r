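test_that("sparse PCA reduces to classical PCA with zero penalties", {
  X <- rand_lowrank(10, 40, 3, seed = 1)
  m <- spca_fit(X, 3)
  top <- eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1:3]
  expect_lt(subspace_gap(m$B, top), 1e-6)
  expect_true(all(abs(crossprod(m$A) - diag(3)) < 1e-6))
})

test_that("sparse PCA shrinks to zero under a huge lasso weight", {
  set.seed(2)
  X <- matrix(rnorm(8 * 30), 8)
  m <- spca_fit(X, 2, lambda1 = 0.1, lambda2 = 1e6)
  expect_equal(max(abs(m$B)), 0)
})

test_that("sparse PCA recovers a planted sparse support", {
  hits <- vapply(1:20, function(r) {
    g <- gen_row_informative(12, 60, 3, snr = 4, n_outliers = 0, seed = 300 + r)
    m <- spca_fit(g$X, 1, lambda1 = 0.1, lambda2 = 2)
    setequal(order(-abs(m$B[, 1]))[1:3], g$support)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("joint-sparse PCA matches PCA reconstruction on clean data", {
  X <- rand_lowrank(10, 40, 3, seed = 3)
  m <- jspca_fit(X, 3, lambda = 0)
  top <- eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1:3]
  err_pca <- sum((X - top %*% crossprod(top, X))^2)
  err_j <- sum((X - m$A %*% crossprod(m$B, X))^2)
  expect_lte(err_j, err_pca * (1 + 1e-3) + 1e-12)
})

test_that("joint-sparse PCA recovers row support under gross outlier samples", {
  f1 <- vapply(1:20, function(r) {
    g <- gen_row_informative(20, 50, 2, snr = 4, n_outliers = 5,
                             outlier_sd = 5, seed = 400 + r)
    m <- jspca_fit(g$X, 3, lambda = 0.1)
    bcimatrix:::.support_f1(order(-sqrt(rowSums(m$B^2)))[1:2], g$support)
  }, numeric(1))
  expect_gte(mean(f1), 0.9)
})

test_that("joint-sparse PCA collapses under a huge penalty", {
  set.seed(4)
  X <- matrix(rnorm(6 * 25), 6)
  m <- jspca_fit(X, 2, lambda = 1e9)
  expect_lt(max(abs(m$B)), 1e-6)
  expect_equal(tail(m$objective_trace, 1), sum(sqrt(colSums(X^2))),
               tolerance = 1e-3)
})

test_that("group-sparse PCA with singleton groups and no penalty equals sparse PCA", {
  X <- rand_lowrank(8, 30, 2, seed = 5)
  ms <- spca_fit(X, 2)
  mg <- jgspca_fit(X, 2, lambda = 0)
  obj <- function(m) sum((X - m$A %*% crossprod(m$B, X))^2)
  expect_equal(obj(mg), obj(ms), tolerance = 1e-8)
})

test_that("group-sparse PCA zeroes irrelevant groups exactly", {
  set.seed(6)
  # structured block of 4 informative rows + pure-noise group of 4
  X <- rbind(rand_lowrank(4, 60, 1, seed = 6) * 4, matrix(rnorm(240, sd = 0.3), 4))
  groups <- list(1:4, 5:8)
  m <- jgspca_fit(X, 1, lambda = 12, groups = groups)
  expect_gt(sum(abs(m$B[1:4, ])), 0)
  expect_equal(sum(abs(m$B[5:8, ])), 0)
  m_all <- jgspca_fit(X, 1, lambda = 1e7, groups = groups)
  expect_equal(max(abs(m_all$B)), 0)
  expect_error(jgspca_fit(X, 1, groups = list(1:4, 4:8)), "partition")
})

test_that("2D-PCA alternation recovers the pooled-scatter eigenspace", {
  set.seed(7)
  trials <- replicate(25, matrix(rnorm(6 * 8), 6, 8), simplify = FALSE)
  m <- orpca_fit(trials, 3)
  Sc <- Reduce(`+`, lapply(trials, crossprod))
  top <- eigen(Sc, symmetric = TRUE)$vectors[, 1:3]
  expect_lt(subspace_gap(m$P, top), 1e-6)
  # full rank, no penalty: perfect reconstruction
  mf <- orpca_fit(trials, 8)
  recon <- sum(vapply(trials, function(X)
    sum((X - X %*% mf$Q %*% t(mf$P))^2), numeric(1)))
  expect_lt(recon, 1e-8)
  # overwhelming ridge drives Q to zero
  mr <- orpca_fit(trials, 3, lambda_a = 1e12)
  expect_lt(max(abs(mr$Q)), 1e-6)
})

test_that("row-sparse 2D-PCA reduces to the ridge-only fit at lambda_b = 0", {
  set.seed(8)
  trials <- replicate(15, matrix(rnorm(4 * 6), 4, 6), simplify = FALSE)
  mo <- orpca_fit(trials, 2, lambda_a = 0.5)
  mj <- rjspca_fit(trials, 2, lambda_a = 0.5, lambda_b = 0)
  expect_equal(tail(mo$objective_trace, 1), tail(mj$objective_trace, 1),
               tolerance = 1e-8)
  # huge row penalty kills every row
  mb <- rjspca_fit(trials, 2, lambda_a = 0.5, lambda_b = 1e9)
  expect_lt(max(abs(mb$Q)), 1e-4)
})

test_that("row-sparse 2D-PCA keeps planted feature columns out of the discard set", {
  keeps <- vapply(1:20, function(r) {
    g <- gen_row_informative(20, 50, 2, snr = 4, n_outliers = 5,
                             outlier_sd = 5, seed = 500 + r)
    trials1 <- lapply(seq_len(ncol(g$X)), function(i) matrix(g$X[, i], nrow = 1))
    m <- rjspca_fit(trials1, 3, lambda_a = 0.1, lambda_b = 10)
    !any(g$support %in% m$discarded)
  }, logical(1))
  expect_gte(mean(keeps), 0.9)
})

test_that("principal component pursuit separates low-rank from sparse", {
  # clean low-rank input: no sparse component is invented
  L <- rand_lowrank(40, 40, 2, seed = 9)
  dec <- rpca_decompose(L)
  expect_lt(sqrt(sum(dec$S^2)) / sqrt(sum(L^2)), 1e-4)
  expect_lt(sqrt(sum((dec$L - L)^2)) / sqrt(sum(L^2)), 1e-4)
  # corrupted instance: exact recovery at the usual scaling
  g <- gen_lowrank_sparse(80, 80, 3, 0.05, amplitude = 10, seed = 9)
  d2 <- rpca_decompose(g$X)
  expect_lt(sqrt(sum((d2$L - g$L0)^2)) / sqrt(sum(g$L0^2)), 1e-3)
  expect_lt(d2$primal_residual, 1e-6)
  # zero input
  d0 <- rpca_decompose(matrix(0, 4, 5))
  expect_equal(d0$L, matrix(0, 4, 5))
  expect_equal(d0$S, matrix(0, 4, 5))
})

test_that("projection applies X Q and reports its own reconstruction error", {
  set.seed(10)
  trials <- replicate(10, matrix(rnorm(3 * 5), 3, 5), simplify = FALSE)
  mf <- orpca_fit(trials, 5)
  X <- trials[[1]]
  expect_equal(X %*% mf$Q %*% t(mf$P), X, tolerance = 1e-8)
  expect_equal(project(mf, matrix(0, 3, 5)), matrix(0, 3, 5))
  m2 <- orpca_fit(trials, 2)
  expect_equal(project(m2, X), X %*% m2$Q)
  expect_error(project(m2, matrix(0, 3, 4)), "columns")
})

test_that("every decomposition objective trace is non-increasing", {
  set.seed(11)
  X <- rand_lowrank(8, 40, 2, seed = 11) + matrix(rnorm(320, sd = 0.2), 8)
  trials <- replicate(12, matrix(rnorm(4 * 6), 4, 6), simplify = FALSE)
  fits <- list(
    spca_fit(X, 2, lambda1 = 0.2, lambda2 = 0.5),
    jspca_fit(X, 2, lambda = 0.5),
    jgspca_fit(X, 2, lambda = 0.5, groups = list(1:3, 4:6, 7:8)),
    orpca_fit(trials, 2, lambda_a = 0.3),
    rjspca_fit(trials, 2, lambda_a = 0.3, lambda_b = 0.3)
  )
  for (f in fits) {
    expect_true(all(diff(f$objective_trace) <= 1e-9 * pmax(1, abs(f$objective_trace[-1]))))
  }
})
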