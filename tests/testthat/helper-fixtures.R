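# Shared deterministic fixtures built in code.

# orthonormal p x k matrix from a seeded Gaussian draw
rand_orth <- function(p, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * k), p)))
}

# exact rank-k data matrix, columns are samples
rand_lowrank <- function(p, n, k, seed = 1) {
  U <- rand_orth(p, k, seed)
  set.seed(seed + 1)
  U %*% matrix(rnorm(k * n), k)
}

# largest principal angle cosine gap between two subspaces (0 = equal span)
subspace_gap <- function(A, B) {
  QA <- qr.Q(qr(A)); QB <- qr.Q(qr(B))
  1 - min(svd(crossprod(QA, QB))$d)
}

# two-class trial set with swapped dominant-channel covariances
make_class_trials <- function(n_per_class = 20, channels = 4, samples = 300,
                              strength = 4, seed = 1) {
  spec <- synthetic_spec(
    n_trials = n_per_class, channels = channels, samples = samples,
    class_covs = class_spatial_covs(channels, 2, strength = strength),
    rhythm_bands = NULL, seed = seed)
  gen_trials(spec)
}

# small separable 2-class feature tensor of 2 x 3 matrices
make_sep_features <- function(n_per_class = 30, gap = 0.8, seed = 1) {
  set.seed(seed)
  feats <- lapply(seq_len(2 * n_per_class), function(i)
    matrix(rnorm(6, mean = ifelse(i <= n_per_class, gap, -gap)), 2, 3))
  feature_tensor(feats, rep(c(1, 2), each = n_per_class))
}
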