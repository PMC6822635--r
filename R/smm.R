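#' Support matrix machines
#'
#' Margin classifiers that keep the regression coefficient in matrix form.
#' [svm_baseline_fit()] is the vectorized linear soft-margin SVM reference
#' (the trace identity `tr(W'X) = vec(W)'vec(X)` makes it the exact
#' vector equivalent).  [rsmm_fit_binary()] is the robust support matrix
#' machine: hinge loss plus an l2,1 row penalty and a nuclear-norm penalty
#' on `W`, trained by consensus ADMM whose three blocks are an exact
#' proximal SVM (dual SMO), singular value thresholding, and the row-wise
#' group soft threshold.  Multiclass problems are handled one-vs-rest.
#'
#' @name support-matrix-machines
NULL

# Dual solver for min_{D, b} 0.5 ||D||^2 + Cp * sum_i max(0, m_i - y_i(<D, x_i> + b)).
# K is the Gram matrix of the rows of the design; alpha may warm-start.
# Returns the dual variables, f = K (alpha * y), the offset b and the KKT gap.
.smo_hinge <- function(K, y, m, Cp, alpha = NULL, tol = 1e-8, max_iter = NULL) {
  n <- length(y)
  if (is.null(alpha)) alpha <- numeric(n)
  alpha <- pmin(pmax(alpha, 0), Cp)
  if (is.null(max_iter)) max_iter <- 500L * n
  f <- as.vector(K %*% (alpha * y))
  tiny <- 1e-12 * max(Cp, 1)
  gap <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ygi <- y * m - f
    up <- (y > 0 & alpha < Cp - tiny) | (y < 0 & alpha > tiny)
    lo <- (y > 0 & alpha > tiny) | (y < 0 & alpha < Cp - tiny)
    if (!any(up) || !any(lo)) { gap <- 0; break }
    i <- which(up)[which.max(ygi[up])]
    j <- which(lo)[which.min(ygi[lo])]
    gap <- ygi[i] - ygi[j]
    if (gap < tol) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_step <- gap / max(eta, 1e-12)
    t_step <- min(t_step,
                  if (y[i] > 0) Cp - alpha[i] else alpha[i],
                  if (y[j] > 0) alpha[j] else Cp - alpha[j])
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    f <- f + t_step * (K[, i] - K[, j])
  }
  ygi <- y * m - f
  free <- alpha > tiny & alpha < Cp - tiny
  b <- if (any(free)) {
    mean(ygi[free])
  } else {
    up <- (y > 0 & alpha < Cp - tiny) | (y < 0 & alpha > tiny)
    lo <- (y > 0 & alpha > tiny) | (y < 0 & alpha < Cp - tiny)
    hi <- if (any(up)) max(ygi[up]) else min(ygi[lo])
    lw <- if (any(lo)) min(ygi[lo]) else max(ygi[up])
    (hi + lw) / 2
  }
  list(alpha = alpha, f = f, b = b, iterations = it, gap = max(gap, 0))
}

.feature_design <- function(features) {
  stopifnot(inherits(features, "feature_tensor"))
  if (!length(features$features)) stop("empty feature tensor", call. = FALSE)
  list(Xv = flatten_features(features),
       shape = dim(features$features[[1]]),
       labels = features$labels)
}

.new_smm <- function(classes, W, b, gamma, tau, C, shape, trace, method,
                     extra = list()) {
  structure(c(list(classes = classes, W = W, b = b, gamma = gamma, tau = tau,
                   C = C, shape = shape, solver_trace = trace, method = method),
              extra),
            class = "smm_model")
}

#' @export
print.smm_model <- function(x, ...) {
  cat(sprintf("smm_model (%s): %d classes, W is %d x %d\n",
              x$method, length(x$classes), x$shape[1], x$shape[2]))
  cat(sprintf("gamma = %g, tau = %g, C = %g\n", x$gamma, x$tau, x$C))
  invisible(x)
}

#' Linear soft-margin SVM baseline on vectorized feature matrices
#'
#' Trains `argmin 0.5 tr(W'W) + C sum_i max(0, 1 - y_i(tr(W'X_i) + b))` on
#' vectorized trials (one-vs-rest for more than two classes) by an exact
#' dual SMO solver, and stores `W` reshaped back to the trial matrix shape.
#'
#' @param features a [feature_tensor()] with at least two classes.
#' @param C hinge weight, > 0.
#' @return An `smm_model` with one `(W, b)` pair per class.
#' @export
svm_baseline_fit <- function(features, C = 1) {
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  d <- .feature_design(features)
  classes <- sort(unique(d$labels))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  K <- tcrossprod(d$Xv)
  fit_one <- function(y) {
    res <- .smo_hinge(K, y, m = rep(1, length(y)), Cp = C)
    Wv <- as.vector(crossprod(d$Xv, res$alpha * y))
    margins <- y * (as.vector(d$Xv %*% Wv) + res$b)
    list(W = matrix(Wv, d$shape[1], d$shape[2]), b = res$b,
         objective = 0.5 * sum(Wv^2) + C * hinge_sum(margins))
  }
  if (length(classes) == 2) {
    y <- ifelse(d$labels == classes[1], 1, -1)
    f <- fit_one(y)
    W <- list(f$W, -f$W); b <- c(f$b, -f$b); trace <- f$objective
  } else {
    fits <- lapply(classes, function(cl) fit_one(ifelse(d$labels == cl, 1, -1)))
    W <- lapply(fits, `[[`, "W")
    b <- vapply(fits, `[[`, numeric(1), "b")
    trace <- vapply(fits, `[[`, numeric(1), "objective")
  }
  .new_smm(classes, W, b, gamma = 0, tau = 0, C = C, d$shape, trace, "svm")
}

# One binary robust SMM problem by consensus ADMM.
.rsmm_admm <- function(Xv, y, shape, gamma, tau, C, rho = 1,
                       tol = 1e-4, max_iter = 500, inner_tol = 1e-8) {
  p <- shape[1]; q <- shape[2]
  dd <- p * q
  K <- tcrossprod(Xv)
  Z <- matrix(0, p, q)
  U0 <- U1 <- U2 <- matrix(0, p, q)
  alpha <- numeric(length(y))
  b <- 0
  trace <- numeric(0)
  best <- NULL
  best_obj <- Inf
  converged <- FALSE
  residuals <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("primal", "dual")))
  for (it in seq_len(max_iter)) {
    # hinge block: proximal SVM around V0 = Z - U0
    V0 <- Z - U0
    m <- 1 - y * as.vector(Xv %*% as.vector(V0))
    sol <- .smo_hinge(K, y, m, Cp = C / rho, alpha = alpha, tol = inner_tol)
    alpha <- sol$alpha
    b <- sol$b
    W0 <- V0 + matrix(as.vector(crossprod(Xv, alpha * y)), p, q)
    W1 <- prox_nuclear(Z - U1, tau / rho)
    W2 <- prox_row_l21(Z - U2, gamma / rho)
    Z_new <- (W0 + U0 + W1 + U1 + W2 + U2) / 3
    r <- sqrt(sum((W0 - Z_new)^2) + sum((W1 - Z_new)^2) + sum((W2 - Z_new)^2))
    s <- rho * sqrt(3) * sqrt(sum((Z_new - Z)^2))
    Z <- Z_new
    U0 <- U0 + W0 - Z
    U1 <- U1 + W1 - Z
    U2 <- U2 + W2 - Z
    margins <- y * (as.vector(Xv %*% as.vector(Z)) + b)
    obj <- gamma * l21_norm(Z) + tau * nuclear_norm(Z) + C * hinge_sum(margins)
    # ADMM iterates are not a descent sequence; the solver returns (and
    # traces) the incumbent: the best-objective iterate seen so far
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(W = Z, b = b, W_lowrank = W1, W_sparse = W2)
    }
    trace <- c(trace, best_obj)
    residuals <- rbind(residuals, c(r, s))
    scale_ref <- max(1, sqrt(sum(Z^2)))
    if (max(r, s) < tol * scale_ref) { converged <- TRUE; break }
    # residual balancing keeps the two residuals within a decade
    if (r > 10 * s) {
      rho <- rho * 2; U0 <- U0 / 2; U1 <- U1 / 2; U2 <- U2 / 2
      alpha <- pmin(alpha, C / rho)
    } else if (s > 10 * r) {
      rho <- rho / 2; U0 <- U0 * 2; U1 <- U1 * 2; U2 <- U2 * 2
    }
  }
  list(W = best$W, b = best$b, W_lowrank = best$W_lowrank, W_sparse = best$W_sparse,
       trace = trace, residuals = residuals, converged = converged)
}

#' Robust support matrix machine, binary
#'
#' Minimizes `gamma ||W||_{2,1} + tau ||W||_* +
#' C sum_i max(0, 1 - y_i(tr(W'X_i) + b))` over a matrix `W` and a free
#' offset `b`.  The consensus ADMM alternates three blocks: an exact
#' proximal linear SVM in vectorized space (dual SMO, `1e-8` inner
#' tolerance) for the hinge, singular value thresholding for the nuclear
#' penalty, and row-wise group soft thresholding for the l2,1 penalty,
#' with residual balancing of the penalty parameter (started at 1).
#'
#' @param features a [feature_tensor()] with exactly two classes; the
#'   lower class identifier is mapped to +1.
#' @param gamma l2,1 penalty weight.
#' @param tau nuclear-norm penalty weight.
#' @param C hinge weight, > 0.
#' @param tol ADMM residual tolerance.
#' @param max_iter ADMM iteration cap.
#' @return An `smm_model`.  The returned `W`, `b` are the best-objective
#'   (incumbent) iterate; `solver_trace` holds the incumbent objective per
#'   iteration (non-increasing by construction), `residuals` the raw
#'   primal/dual ADMM residuals, and `W_lowrank` / `W_sparse` the
#'   structured proximal blocks of the incumbent.
#' @export
rsmm_fit_binary <- function(features, gamma = 0.1, tau = 0.1, C = 1,
                            tol = 1e-4, max_iter = 500) {
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (gamma < 0 || tau < 0) stop("penalties must be nonnegative", call. = FALSE)
  d <- .feature_design(features)
  classes <- sort(unique(d$labels))
  if (length(classes) != 2) stop("binary fit requires exactly two classes", call. = FALSE)
  y <- ifelse(d$labels == classes[1], 1, -1)
  fit <- .rsmm_admm(d$Xv, y, d$shape, gamma, tau, C, tol = tol, max_iter = max_iter)
  .new_smm(classes, list(fit$W, -fit$W), c(fit$b, -fit$b), gamma, tau, C,
           d$shape, fit$trace, "rsmm",
           extra = list(residuals = fit$residuals, converged = fit$converged,
                        W_lowrank = list(fit$W_lowrank), W_sparse = list(fit$W_sparse)))
}

#' Robust support matrix machine, multiclass (one-vs-rest)
#'
#' Solves one binary robust SMM per class with targets +1 for that class
#' and -1 for the rest, sharing `gamma`, `tau` and `C`; two-class input
#' reduces to [rsmm_fit_binary()].
#'
#' @inheritParams rsmm_fit_binary
#' @param features a [feature_tensor()] with at least two classes.
#' @return An `smm_model` with one `(W, b)` pair per class.
#' @export
rsmm_fit_multiclass <- function(features, gamma = 0.1, tau = 0.1, C = 1,
                                tol = 1e-4, max_iter = 500) {
  d <- .feature_design(features)
  classes <- sort(unique(d$labels))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  if (length(classes) == 2)
    return(rsmm_fit_binary(features, gamma, tau, C, tol, max_iter))
  counts <- table(d$labels)
  small <- names(counts)[counts < 2]
  if (length(small))
    warning("class(es) with fewer than 2 samples: ", paste(small, collapse = ", "))
  fits <- lapply(classes, function(cl) {
    y <- ifelse(d$labels == cl, 1, -1)
    .rsmm_admm(d$Xv, y, d$shape, gamma, tau, C, tol = tol, max_iter = max_iter)
  })
  .new_smm(classes, lapply(fits, `[[`, "W"), vapply(fits, `[[`, numeric(1), "b"),
           gamma, tau, C, d$shape, lapply(fits, `[[`, "trace"), "rsmm",
           extra = list(converged = vapply(fits, `[[`, logical(1), "converged"),
                        W_lowrank = lapply(fits, `[[`, "W_lowrank"),
                        W_sparse = lapply(fits, `[[`, "W_sparse")))
}

#' Per-class decision values of a support matrix machine
#'
#' @param model an `smm_model`.
#' @param features a [feature_tensor()] with matching trial shape.
#' @return numeric matrix, trials x classes, of `tr(W_j'X) + b_j`.
#' @export
smm_decision <- function(model, features) {
  stopifnot(inherits(model, "smm_model"))
  d <- .feature_design(features)
  if (!all(d$shape == model$shape))
    stop("feature shape does not match the training shape", call. = FALSE)
  vals <- vapply(seq_along(model$classes), function(j) {
    as.vector(d$Xv %*% as.vector(model$W[[j]])) + model$b[j]
  }, numeric(nrow(d$Xv)))
  matrix(vals, nrow = nrow(d$Xv),
         dimnames = list(NULL, as.character(model$classes)))
}

#' Predict class labels with a support matrix machine
#'
#' The label is `argmax_j tr(W_j'X) + b_j`; exact ties go to the lowest
#' class identifier.
#'
#' @inheritParams smm_decision
#' @return vector of predicted labels (same type as the training labels).
#' @export
smm_predict <- function(model, features) {
  dec <- smm_decision(model, features)
  model$classes[apply(dec, 1, which.max)]
}

#' Grid search over robust SMM hyperparameters
#'
#' Evaluates every combination by stratified cross-validated accuracy and
#' returns the grid with the best row first.  Ties prefer the smaller
#' penalties.
#'
#' @param features a [feature_tensor()].
#' @param gammas,taus,Cs candidate values.
#' @param k folds.
#' @param seed fold seed.
#' @return data.frame of combinations and mean CV accuracy, sorted.
#' @export
rsmm_grid <- function(features, gammas = 10^(-3:2), taus = 10^(-3:2),
                      Cs = 1, k = 3, seed = 1L) {
  grid <- expand.grid(gamma = gammas, tau = taus, C = Cs)
  folds <- stratified_kfold(features$labels, k, seed)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    accs <- vapply(folds, function(val) {
      tr <- setdiff(seq_along(features$labels), val)
      model <- rsmm_fit_multiclass(features[tr], grid$gamma[i], grid$tau[i], grid$C[i])
      mean(smm_predict(model, features[val]) == features$labels[val])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  grid[order(-grid$accuracy, grid$gamma, grid$tau, grid$C), ]
}
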