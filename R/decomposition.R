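#' Sparse and robust principal-component decompositions
#'
#' A family of penalized reconstructions of a feature matrix `X` (rows are
#' features, columns are samples) or of a set of trial matrices:
#'
#' * [spca_fit()] — sparse PCA: ridge + lasso penalties on the loadings.
#' * [jspca_fit()] — joint-sparse PCA: l2,1 norms on both the residual
#'   (columnwise, robust to outlier samples) and the loadings (row
#'   sparsity, joint feature selection).
#' * [jgspca_fit()] — group-sparse PCA: whole predefined feature groups
#'   are selected or dropped together.
#' * [orpca_fit()] — two-dimensional PCA on trial matrices with a ridge
#'   penalty that decorrelates successive components.
#' * [rjspca_fit()] — adds an l2,1 row penalty to [orpca_fit()] so that
#'   uninformative feature columns are discarded outright.
#' * [rpca_decompose()] — principal component pursuit: low-rank plus
#'   sparse decomposition by an inexact augmented Lagrangian method.
#'
#' All iterative fits carry an `objective_trace`; each solver is a
#' majorize-minimize or exact alternating scheme, so traces are
#' non-increasing.
#'
#' @name matrix-decompositions
NULL

# orthonormal factor of the Procrustes problem max tr(A' M) over A'A = I
.procrustes <- function(M, fallback) {
  s <- svd(M)
  if (!length(s$d) || s$d[1] < 1e-300) return(fallback)
  s$u %*% t(s$v)
}

# min-norm solve of (symmetric PSD) S x = c columns
.psd_solve <- function(S, C, ridge = 0) {
  if (ridge > 0) return(solve(S + ridge * diag(nrow(S)), C))
  e <- eigen(S, symmetric = TRUE)
  tol <- 1e-12 * max(e$values, 0)
  inv <- ifelse(e$values > tol, 1 / e$values, 0)
  e$vectors %*% (inv * (t(e$vectors) %*% C))
}

.top_eigvecs <- function(S, k) {
  eigen(S, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
}

# epsilon-smoothed absolute value, centred so that .huber(0, eps) = 0
.huber <- function(u, eps) ifelse(u >= eps, u - eps / 2, u^2 / (2 * eps))

.new_loadings <- function(A, B, lambda1, lambda2, trace, converged) {
  structure(list(A = A, B = B, lambda1 = lambda1, lambda2 = lambda2,
                 objective_trace = trace, converged = converged,
                 iterations = length(trace)),
            class = "loadings_model")
}

#' @export
print.loadings_model <- function(x, ...) {
  cat(sprintf("loadings_model: %d x %d loadings, %d iterations, %s\n",
              nrow(x$B), ncol(x$B), x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("nonzero loading rows: %d / %d\n",
              sum(sqrt(rowSums(x$B^2)) > 1e-8), nrow(x$B)))
  invisible(x)
}

#' Sparse PCA by alternating elastic-net regressions
#'
#' Minimizes `sum_i ||x_i - A B' x_i||^2 + lambda1 sum_j ||b_j||^2 +
#' sum_j lambda2_j ||b_j||_1` subject to `A'A = I`.  Given `A`, each
#' loading column solves an elastic-net problem (coordinate descent; a
#' closed-form minimum-norm solve when its lasso weight is zero); given
#' `B`, `A` is the Procrustes rotation from the SVD of `(XX')B`.
#' Initialization is classical PCA of `X`.
#'
#' @param X numeric p x n matrix, columns are samples.
#' @param k number of components, `k <= min(p, n)`.
#' @param lambda1 ridge weight (shared).
#' @param lambda2 lasso weight(s), scalar or length-`k` vector.
#' @param max_iter,tol stopping rule: `max |delta B| < tol` or `max_iter`.
#' @return A `loadings_model` with orthonormal `A`, sparse loadings `B`,
#'   and a non-increasing `objective_trace`.
#' @export
spca_fit <- function(X, k, lambda1 = 0, lambda2 = 0, max_iter = 200, tol = 1e-6) {
  X <- .check_matrix(X, "X")
  p <- nrow(X); n <- ncol(X)
  if (k < 1 || k > min(p, n)) stop("`k` must satisfy 1 <= k <= min(p, n)", call. = FALSE)
  if (lambda1 < 0 || any(lambda2 < 0)) stop("penalties must be nonnegative", call. = FALSE)
  lambda2 <- rep_len(lambda2, k)
  S <- tcrossprod(X)
  A <- .top_eigvecs(S, k)
  B <- A
  M <- S + lambda1 * diag(p)
  objective <- function(A, B) {
    sum((X - A %*% crossprod(B, X))^2) + lambda1 * sum(B^2) +
      sum(lambda2 * colSums(abs(B)))
  }
  trace <- objective(A, B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    B_old <- B
    C <- S %*% A
    for (j in seq_len(k)) {
      if (lambda2[j] == 0) {
        B[, j] <- if (lambda1 > 0) solve(M, C[, j]) else .psd_solve(S, C[, j])
      } else {
        B[, j] <- .lasso_cd(M, C[, j], lambda2[j] / 2, B[, j])
      }
    }
    A <- .procrustes(S %*% B, A)[, seq_len(k), drop = FALSE]
    trace <- c(trace, objective(A, B))
    if (max(abs(B - B_old)) < tol) { converged <- TRUE; break }
  }
  .new_loadings(A, B, lambda1, lambda2, trace, converged)
}

# coordinate descent for min b' M b - 2 b' c + 2 t ||b||_1
.lasso_cd <- function(M, c, t, b, max_pass = 1000, tol = 1e-10) {
  p <- length(c)
  Mb <- as.vector(M %*% b)
  for (pass in seq_len(max_pass)) {
    delta_max <- 0
    for (m in seq_len(p)) {
      if (M[m, m] <= 0) next
      r <- c[m] - Mb[m] + M[m, m] * b[m]
      b_new <- sign(r) * max(abs(r) - t, 0) / M[m, m]
      d <- b_new - b[m]
      if (d != 0) {
        Mb <- Mb + M[, m] * d
        b[m] <- b_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  b
}

#' Joint-sparse PCA (l2,1 loss and l2,1 loadings penalty)
#'
#' Minimizes `||X - A B' X||_{2,1} + lambda ||B||_{2,1}` with `A'A = I`,
#' where the loss l2,1 norm runs over residual columns (samples), making
#' whole outlier samples cheap to ignore, and the penalty runs over rows
#' of `B` (joint feature selection).  Solved by iteratively reweighted
#' least squares: both norms are epsilon-smoothed (Huber, `eps = 1e-6`);
#' given the weights the loadings have a closed form and `A` is a weighted
#' Procrustes rotation.  The recorded objective is the smoothed one, which
#' the MM iteration decreases monotonically.
#'
#' @inheritParams spca_fit
#' @param lambda l2,1 penalty weight on the loadings rows.
#' @param eps IRLS smoothing floor.
#' @return A `loadings_model`.
#' @export
jspca_fit <- function(X, k, lambda = 0, max_iter = 300, tol = 1e-6, eps = 1e-6) {
  X <- .check_matrix(X, "X")
  p <- nrow(X); n <- ncol(X)
  if (k < 1 || k > min(p, n)) stop("`k` must satisfy 1 <= k <= min(p, n)", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  S0 <- tcrossprod(X)
  A <- .top_eigvecs(S0, k)
  B <- A
  objective <- function(A, B) {
    R <- X - A %*% crossprod(B, X)
    sum(.huber(sqrt(colSums(R^2)), eps)) +
      lambda * sum(.huber(sqrt(rowSums(B^2)), eps))
  }
  trace <- objective(A, B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    R <- X - A %*% crossprod(B, X)
    d <- 1 / (2 * pmax(sqrt(colSums(R^2)), eps))
    w <- 1 / (2 * pmax(sqrt(rowSums(B^2)), eps))
    S_D <- X %*% (d * t(X))
    B <- if (lambda > 0) solve(S_D + lambda * diag(w, p), S_D %*% A)
         else .psd_solve(S_D, S_D %*% A)
    A <- .procrustes(S_D %*% B, A)[, seq_len(k), drop = FALSE]
    obj <- objective(A, B)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (abs(prev - obj) < tol * max(1, abs(prev))) { converged <- TRUE; break }
  }
  .new_loadings(A, B, lambda1 = 0, lambda2 = lambda, trace, converged)
}

#' Group-sparse PCA
#'
#' Minimizes `||X - A B' X||_F^2 + lambda sum_g eta_g ||B_g||_F` with
#' `A'A = I`, where the rows of `B` are partitioned into feature groups
#' `g` and `eta_g = sqrt(|g|)`.  The loadings step is proximal gradient
#' with a blockwise group soft-threshold (step `1/L`, `L = 2 lambda_max(S)`),
#' so entire groups become exactly zero; `A` is updated by Procrustes.
#'
#' @inheritParams jspca_fit
#' @param groups list of integer vectors partitioning `1:p`.
#' @return A `loadings_model` with an extra element `groups`.
#' @export
jgspca_fit <- function(X, k, lambda = 0, groups = as.list(seq_len(nrow(X))),
                       max_iter = 200, tol = 1e-7) {
  X <- .check_matrix(X, "X")
  p <- nrow(X); n <- ncol(X)
  if (k < 1 || k > min(p, n)) stop("`k` must satisfy 1 <= k <= min(p, n)", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  all_idx <- sort(unlist(groups))
  if (length(all_idx) != p || any(all_idx != seq_len(p)) || anyDuplicated(unlist(groups)))
    stop("`groups` must partition the feature indices 1:p without overlap", call. = FALSE)
  eta <- sqrt(lengths(groups))
  S <- tcrossprod(X)
  L <- 2 * max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  A <- .top_eigvecs(S, k)
  B <- A
  penalty <- function(B) {
    lambda * sum(vapply(seq_along(groups), function(g)
      eta[g] * sqrt(sum(B[groups[[g]], , drop = FALSE]^2)), numeric(1)))
  }
  objective <- function(A, B) sum((X - A %*% crossprod(B, X))^2) + penalty(B)
  group_prox <- function(B, t_scale) {
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      blk <- B[idx, , drop = FALSE]
      nb <- sqrt(sum(blk^2))
      B[idx, ] <- if (nb > 0) blk * max(1 - t_scale * eta[g] / nb, 0) else 0
    }
    B
  }
  trace <- objective(A, B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    B_old <- B
    SA <- S %*% A
    for (inner in seq_len(50)) {
      B_prev <- B
      grad <- 2 * (S %*% B - SA)
      B <- group_prox(B - grad / L, lambda / L)
      if (max(abs(B - B_prev)) < 1e-9) break
    }
    A <- .procrustes(S %*% B, A)[, seq_len(k), drop = FALSE]
    trace <- c(trace, objective(A, B))
    if (max(abs(B - B_old)) < tol) { converged <- TRUE; break }
  }
  m <- .new_loadings(A, B, lambda1 = 0, lambda2 = lambda, trace, converged)
  m$groups <- groups
  m
}

#' Reduced representation under a loadings model
#'
#' @param model a `loadings_model`.
#' @param X p x n matrix with the same feature rows as the training data.
#' @return k x n matrix `B'X`.
#' @export
loadings_transform <- function(model, X) {
  stopifnot(inherits(model, "loadings_model"))
  X <- .check_matrix(X, "X")
  if (nrow(X) != nrow(model$B)) stop("feature dimension mismatch", call. = FALSE)
  crossprod(model$B, X)
}

.new_projection <- function(Q, P, lambda_a, lambda_b, trace, converged, discarded = integer(0)) {
  structure(list(Q = Q, P = P, lambda_a = lambda_a, lambda_b = lambda_b,
                 objective_trace = trace, converged = converged,
                 iterations = length(trace), discarded = discarded),
            class = "two_d_projection")
}

#' @export
print.two_d_projection <- function(x, ...) {
  cat(sprintf("two_d_projection: %d x %d, %d iterations, %s\n",
              nrow(x$Q), ncol(x$Q), x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  if (length(x$discarded))
    cat("discarded feature columns:", paste(x$discarded, collapse = ", "), "\n")
  invisible(x)
}

.as_trial_list <- function(trials) {
  if (inherits(trials, "trial_set")) return(trials$trials)
  if (inherits(trials, "feature_tensor")) return(trials$features)
  stopifnot(is.list(trials))
  lapply(trials, function(x) .check_matrix(x, "trial"))
}

#' Outlier-robust two-dimensional PCA
#'
#' Minimizes `sum_j ||X_j - X_j Q P'||_F^2 + lambda_a ||Q||_F^2` over a
#' regression matrix `Q` and an orthonormal projection `P` (both b x k),
#' by exact alternation: a ridge solve for `Q` and a Procrustes rotation
#' for `P`.  With `lambda_a = 0` this is classical 2D-PCA of the pooled
#' column scatter `sum_j X_j' X_j`.
#'
#' @param trials list of a x b matrices (or a `trial_set` / `feature_tensor`).
#' @param k number of components, `k <= b`.
#' @param lambda_a ridge weight.
#' @param max_iter,tol stopping rule on relative objective change.
#' @return A `two_d_projection`.
#' @export
orpca_fit <- function(trials, k, lambda_a = 0, max_iter = 200, tol = 1e-6) {
  rjspca_fit(trials, k, lambda_a = lambda_a, lambda_b = 0,
             max_iter = max_iter, tol = tol)
}

#' Robust joint-sparse two-dimensional PCA
#'
#' Adds a row-sparsity penalty `lambda_b ||Q||_{2,1}` to [orpca_fit()], so
#' that feature columns whose `Q` rows vanish are discarded outright.  The
#' `Q` step is an iteratively reweighted ridge solve (`eps = 1e-6`
#' smoothing); the recorded objective is correspondingly Huber-smoothed in
#' the penalty and decreases monotonically.  Rows of `Q` with norm below
#' `1e-6` times the largest row norm are reported in `discarded`.
#'
#' @inheritParams orpca_fit
#' @param lambda_b l2,1 row-sparsity weight (`0` recovers [orpca_fit()]).
#' @param eps IRLS smoothing floor.
#' @return A `two_d_projection`.
#' @export
rjspca_fit <- function(trials, k, lambda_a = 0, lambda_b = 0,
                       max_iter = 200, tol = 1e-6, eps = 1e-6) {
  Xs <- .as_trial_list(trials)
  if (!length(Xs)) stop("no trials supplied", call. = FALSE)
  b <- ncol(Xs[[1]])
  if (k < 1 || k > b) stop("`k` must satisfy 1 <= k <= ncol(trial)", call. = FALSE)
  if (lambda_a < 0 || lambda_b < 0) stop("penalties must be nonnegative", call. = FALSE)
  Sc <- Reduce(`+`, lapply(Xs, crossprod))
  total <- sum(diag(Sc))
  P <- .top_eigvecs(Sc, k)
  Q <- P
  objective <- function(Q, P) {
    total - 2 * sum(diag(crossprod(P, Sc %*% Q))) + sum(diag(crossprod(Q, Sc %*% Q))) +
      lambda_a * sum(Q^2) +
      (if (lambda_b > 0) lambda_b * sum(.huber(sqrt(rowSums(Q^2)), eps)) else 0)
  }
  trace <- objective(Q, P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    reg <- Sc + lambda_a * diag(b)
    if (lambda_b > 0) {
      w <- 1 / (2 * pmax(sqrt(rowSums(Q^2)), eps))
      reg <- reg + lambda_b * diag(w, b)
      Q <- solve(reg, Sc %*% P)
    } else if (lambda_a > 0) {
      Q <- solve(reg, Sc %*% P)
    } else {
      Q <- .psd_solve(Sc, Sc %*% P)
    }
    P <- .procrustes(Sc %*% Q, P)[, seq_len(k), drop = FALSE]
    obj <- objective(Q, P)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (abs(prev - obj) < tol * max(1, abs(prev))) { converged <- TRUE; break }
  }
  rn <- sqrt(rowSums(Q^2))
  discarded <- if (lambda_b > 0 && max(rn) > 0) which(rn < 1e-6 * max(rn)) else integer(0)
  .new_projection(Q, P, lambda_a, lambda_b, trace, converged, discarded)
}

#' Project a trial matrix onto a fitted 2D subspace
#'
#' @param model a `two_d_projection`.
#' @param trial a x b matrix with `b` matching the training column count.
#' @return a x k matrix `X Q`; the reconstruction is `X Q P'`.
#' @export
project <- function(model, trial) {
  stopifnot(inherits(model, "two_d_projection"))
  trial <- .check_matrix(trial, "trial")
  if (ncol(trial) != nrow(model$Q))
    stop("trial has wrong number of columns for this projection", call. = FALSE)
  trial %*% model$Q
}

#' Apply a 2D projection to every trial of a feature tensor
#'
#' @param model a `two_d_projection`.
#' @param ft a `feature_tensor` (or `trial_set`).
#' @return a `feature_tensor` of projected matrices.
#' @export
project_features <- function(model, ft) {
  Xs <- .as_trial_list(ft)
  labels <- if (inherits(ft, "trial_set") || inherits(ft, "feature_tensor")) ft$labels
            else rep(NA, length(Xs))
  feature_tensor(lapply(Xs, function(X) project(model, X)), labels)
}

#' Low-rank plus sparse decomposition (principal component pursuit)
#'
#' Solves `min ||L||_* + lambda ||S||_1  s.t.  X = L + S` by the inexact
#' augmented Lagrangian method: alternating singular value thresholding on
#' `L`, elementwise soft thresholding on `S`, and a dual update, with the
#' penalty parameter increased geometrically.  The default
#' `lambda = 1 / sqrt(max(m, n))` is the standard universal choice.
#'
#' @param X numeric m x n matrix.
#' @param lambda sparsity trade-off; default `1 / sqrt(max(m, n))`.
#' @param tol feasibility tolerance on `||X - L - S||_F / ||X||_F`.
#' @param max_iter iteration cap.
#' @return list of class `low_rank_sparse` with `L`, `S`, `lambda`,
#'   `iterations`, `primal_residual`.
#' @export
rpca_decompose <- function(X, lambda = NULL, tol = 1e-7, max_iter = 1000) {
  X <- .check_matrix(X, "X")
  m <- nrow(X); n <- ncol(X)
  if (is.null(lambda)) lambda <- 1 / sqrt(max(m, n))
  normX <- sqrt(sum(X^2))
  if (normX == 0) {
    return(structure(list(L = X, S = X, lambda = lambda, iterations = 0L,
                          primal_residual = 0),
                     class = "low_rank_sparse"))
  }
  spec <- svd(X, nu = 0, nv = 0)$d[1]
  Y <- X / max(spec, max(abs(X)) / lambda)
  mu <- 1.25 / spec
  mu_max <- mu * 1e7
  rho <- 1.5
  S <- matrix(0, m, n)
  L <- matrix(0, m, n)
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L <- prox_nuclear(X - S + Y / mu, 1 / mu)
    S <- soft_threshold(X - L + Y / mu, lambda / mu)
    Z <- X - L - S
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_max)
    resid <- sqrt(sum(Z^2)) / normX
    if (resid < tol) break
  }
  structure(list(L = L, S = S, lambda = lambda, iterations = it,
                 primal_residual = resid),
            class = "low_rank_sparse")
}

#' @export
print.low_rank_sparse <- function(x, ...) {
  cat(sprintf("low_rank_sparse: rank(L) = %d, nnz(S) = %d, residual %.2e (%d iterations)\n",
              .num_rank(x$L), sum(x$S != 0), x$primal_residual, x$iterations))
  invisible(x)
}
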