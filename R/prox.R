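#' Norms and proximal operators for matrix-regularized estimation
#'
#' The l2,1 norm (sum of row Euclidean norms) promotes whole-row sparsity;
#' the nuclear norm (sum of singular values) is the convex surrogate for
#' rank.  Both appear as penalties in the sparse decompositions and the
#' support matrix machine, and their proximal operators are the basic
#' solver steps shared across the package.
#'
#' @name prox-operators
NULL

.check_matrix <- function(M, arg = "M") {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (!is.numeric(M)) stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(M))) stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  M
}

.check_threshold <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("threshold `t` must be a single finite nonnegative number", call. = FALSE)
  t
}

#' Sum of row Euclidean norms (l2,1 norm)
#'
#' @param M numeric matrix.
#' @return Nonnegative scalar, \eqn{\sum_i \sqrt{\sum_j M_{ij}^2}}.
#' @examples
#' l21_norm(rbind(c(3, 4), c(0, 0)))  # 5
#' @export
l21_norm <- function(M) {
  M <- .check_matrix(M)
  sum(sqrt(rowSums(M^2)))
}

#' Sum of singular values (nuclear norm)
#'
#' @param M numeric matrix.
#' @return Nonnegative scalar, the sum of singular values of `M`.
#' @export
nuclear_norm <- function(M) {
  M <- .check_matrix(M)
  sum(svd(M, nu = 0, nv = 0)$d)
}

#' Singular value thresholding (proximal operator of the nuclear norm)
#'
#' Computes \eqn{\arg\min_Z \tfrac12\|Z - M\|_F^2 + t\|Z\|_*}: the SVD of
#' `M` with singular values soft-thresholded by `t`.  Singular values below
#' `1e-10` times the largest are treated as exact zeros when reporting rank.
#'
#' @param M numeric matrix.
#' @param t nonnegative threshold.
#' @return Matrix of the same shape as `M`.
#' @export
prox_nuclear <- function(M, t) {
  M <- .check_matrix(M)
  .check_threshold(t)
  if (t == 0) return(M)
  s <- svd(M)
  d <- pmax(s$d - t, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Row-wise group soft threshold (proximal operator of the l2,1 norm)
#'
#' Each row `r` is mapped to `r * max(1 - t / ||r||, 0)`.  Rows that are
#' exactly zero are returned unchanged (no division is attempted).
#'
#' @inheritParams prox_nuclear
#' @return Matrix of the same shape as `M`.
#' @export
prox_row_l21 <- function(M, t) {
  M <- .check_matrix(M)
  .check_threshold(t)
  if (t == 0) return(M)
  rn <- sqrt(rowSums(M^2))
  scale <- ifelse(rn > 0, pmax(1 - t / rn, 0), 0)
  M * scale
}

#' Total hinge loss of a margin sequence
#'
#' @param margins numeric vector of margins \eqn{m_i = y_i(tr(W'X_i) + b)}.
#' @return \eqn{\sum_i \max(0, 1 - m_i)}.
#' @export
hinge_sum <- function(margins) {
  if (any(!is.finite(margins))) stop("margins must be finite", call. = FALSE)
  sum(pmax(0, 1 - margins))
}

#' Elementwise soft threshold
#' @noRd
soft_threshold <- function(M, t) {
  sign(M) * pmax(abs(M) - t, 0)
}

#' Numerical rank at a relative singular-value tolerance
#' @noRd
.num_rank <- function(M, rel_tol = 1e-10) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (!length(d) || d[1] == 0) return(0L)
  sum(d > rel_tol * d[1])
}
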