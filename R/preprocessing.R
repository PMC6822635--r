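#' Sample size with finite-population correction
#'
#' Cochran's formula for the sample size needed to estimate a proportion
#' `p` at margin of error `e` with standard normal variate `Z`:
#' `n0 = Z^2 p (1 - p) / e^2`.  For a finite population of size `N` the
#' corrected size is `n = n0 / (1 + (n0 - 1) / N)`.  The corrected size is
#' rounded up (conservative).
#'
#' @param p estimated proportion in `[0, 1]` (use 0.5 for the maximal size).
#' @param Z standard normal variate (e.g. 2.58 for 99% confidence).
#' @param e margin of error, > 0.
#' @param N optional finite population size.
#' @return list of class `sample_size_spec` with `p, Z, e, N, n0, n`.
#' @examples
#' compute_sample_size(0.5, 2.58, 0.01, N = 4097)
#' @export
compute_sample_size <- function(p, Z, e, N = NULL) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(e) || e <= 0) stop("`e` must be positive", call. = FALSE)
  if (!is.numeric(Z) || Z <= 0) stop("`Z` must be positive", call. = FALSE)
  if (!is.null(N) && (N < 1 || N != round(N))) stop("`N` must be a positive integer", call. = FALSE)
  n0 <- Z^2 * p * (1 - p) / e^2
  n <- if (is.null(N)) ceiling(n0) else ceiling(n0 / (1 + (n0 - 1) / N))
  structure(list(p = p, Z = Z, e = e, N = N, n0 = n0, n = n),
            class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat(sprintf("sample size: n0 = %g (uncorrected)", x$n0))
  if (!is.null(x$N)) cat(sprintf(", n = %d after finite-population correction (N = %d)", x$n, x$N))
  cat("\n")
  invisible(x)
}

#' Split a signal into contiguous near-equal windows
#'
#' Lengths are `floor(total / n)` with the remainder added to the last
#' window, so a 4097-sample signal in 4 windows yields 1024, 1024, 1024,
#' 1025.
#'
#' @param total_length total number of samples.
#' @param n_windows number of windows, `1 <= n_windows <= total_length`.
#' @return integer vector of window lengths summing to `total_length`.
#' @export
segment_signal <- function(total_length, n_windows) {
  stopifnot(n_windows >= 1, total_length >= 1)
  if (n_windows > total_length)
    stop("`n_windows` may not exceed `total_length`", call. = FALSE)
  base <- total_length %/% n_windows
  lens <- rep(base, n_windows)
  lens[n_windows] <- lens[n_windows] + total_length %% n_windows
  as.integer(lens)
}

#' Variance-weighted sample allocation across windows
#'
#' Window `i` with `N_i` available samples and per-channel variances
#' `Var[i, ]` receives the allocation fraction
#' `N_i * sqrt(sum_j Var[i,j]^2) / sum_k N_k * sqrt(sum_j Var[k,j]^2)`.
#' Integer counts are obtained by largest-remainder rounding so they sum
#' exactly to `budget` (ties broken by lower window index).
#'
#' @param N_i positive per-window sizes.
#' @param Var nonnegative k x p matrix of per-window per-channel variances.
#' @param budget total integer sample budget.
#' @return list of class `window_plan` with `fractions` and `counts`.
#' @export
allocate_samples <- function(N_i, Var, budget) {
  Var <- as.matrix(Var)
  stopifnot(all(N_i > 0), nrow(Var) == length(N_i), budget >= 0)
  if (any(Var < 0)) stop("variances must be nonnegative", call. = FALSE)
  w <- N_i * sqrt(rowSums(Var^2))
  if (sum(w) == 0)
    stop("degenerate allocation: all window variances are zero", call. = FALSE)
  fractions <- w / sum(w)
  raw <- fractions * budget
  counts <- floor(raw)
  short <- budget - sum(counts)
  if (short > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  structure(list(N_i = N_i, Var = Var, fractions = fractions,
                 counts = as.integer(counts), budget = budget),
            class = "window_plan")
}

#' Default 4-40 Hz filter bank
#'
#' Nine contiguous 4 Hz bands from 4 to 40 Hz, the conventional FBCSP
#' grid covering theta through low gamma.
#'
#' @param filter_order Butterworth order (applied zero-phase).
#' @return list of class `filterbank_spec` with `bands` and `filter_order`.
#' @export
default_filterbank <- function(filter_order = 4) {
  bands <- lapply(seq(4, 36, by = 4), function(lo) c(lo, lo + 4))
  filterbank_spec(bands, filter_order)
}

#' Filter bank specification
#'
#' @param bands list of `(low, high)` Hz pairs, `0 < low < high`.
#' @param filter_order positive integer Butterworth order.
#' @export
filterbank_spec <- function(bands, filter_order = 4) {
  stopifnot(filter_order >= 1)
  for (b in bands) stopifnot(length(b) == 2, b[1] > 0, b[1] < b[2])
  structure(list(bands = bands, filter_order = as.integer(filter_order)),
            class = "filterbank_spec")
}

#' Band-pass filter a trial set through a filter bank
#'
#' Applies a zero-phase Butterworth band-pass (forward-backward filtering)
#' per band and channel; shapes are preserved.
#'
#' @param ts a [trial_set()].
#' @param spec a [filterbank_spec()]; band edges must be below `ts$fs / 2`.
#' @return list of `trial_set` objects, one per band.
#' @export
bandpass_filterbank <- function(ts, spec = default_filterbank()) {
  stopifnot(inherits(ts, "trial_set"), inherits(spec, "filterbank_spec"))
  nyq <- ts$fs / 2
  for (b in spec$bands)
    if (b[2] >= nyq)
      stop(sprintf("band edge %g Hz is not below the Nyquist frequency %g Hz", b[2], nyq),
           call. = FALSE)
  lapply(spec$bands, function(b) {
    flt <- signal::butter(spec$filter_order, b / nyq, type = "pass")
    filtered <- lapply(ts$trials, function(X) {
      t(apply(X, 1, function(row) signal::filtfilt(flt, row)))
    })
    trial_set(filtered, ts$labels, ts$fs, ts$channel_names)
  })
}

.trial_cov <- function(X) {
  S <- tcrossprod(X)
  tr <- sum(diag(S))
  if (tr <= 0) stop("trial with zero total power: covariance undefined", call. = FALSE)
  S / tr
}

#' Fit common spatial patterns for a class pair
#'
#' Average trace-normalized trial covariances per class and solve the
#' generalized eigenproblem `Sigma1 w = lambda (Sigma1 + Sigma2) w`.  Rows
#' of `filters` are spatial filters sorted by eigenvalue descending, so the
#' first filters maximize class-1 variance share and the last maximize
#' class-2's.  The filters whiten the pooled covariance.  A ridge of
#' `1e-8 * I` is added if the pooled covariance is numerically singular.
#'
#' @param ts a [trial_set()] with at least two trials of each class.
#' @param class_pair the two labels to contrast (default: first two
#'   distinct labels).
#' @return list of class `csp_model` with `filters`, `eigenvalues`,
#'   `patterns` (the inverse transpose of `filters`), and `class_pair`.
#' @export
csp_fit <- function(ts, class_pair = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(class_pair)) {
    u <- unique(ts$labels)
    if (length(u) < 2) stop("need two classes to fit CSP", call. = FALSE)
    class_pair <- u[1:2]
  }
  i1 <- which(ts$labels == class_pair[1])
  i2 <- which(ts$labels == class_pair[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("need at least 2 trials per class", call. = FALSE)
  S1 <- Reduce(`+`, lapply(ts$trials[i1], .trial_cov)) / length(i1)
  S2 <- Reduce(`+`, lapply(ts$trials[i2], .trial_cov)) / length(i2)
  Sp <- S1 + S2
  ep <- eigen(Sp, symmetric = TRUE)
  if (min(ep$values) < 1e-12 * max(ep$values)) {
    Sp <- Sp + 1e-8 * diag(nrow(Sp))
    ep <- eigen(Sp, symmetric = TRUE)
  }
  # whitening transform P: P Sp P' = I
  P <- (1 / sqrt(ep$values)) * t(ep$vectors)
  M <- P %*% S1 %*% t(P)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  filters <- t(em$vectors) %*% P
  structure(
    list(filters = filters,
         eigenvalues = pmin(pmax(em$values, 0), 1),
         patterns = solve(t(filters) %*% filters, t(filters)),
         class_pair = class_pair,
         class_covs = list(S1, S2), pooled_cov = Sp),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("csp_model: %d filters, classes %s vs %s\n",
              nrow(x$filters), x$class_pair[1], x$class_pair[2]))
  cat("top eigenvalues:", paste(round(utils::head(x$eigenvalues, 4), 3), collapse = " "), "\n")
  invisible(x)
}

#' CSP log-variance features
#'
#' Projects each trial onto the `m` top and `m` bottom spatial filters and
#' takes the log of each projected component's share of the total projected
#' variance.  Zero-variance components are guarded by a small epsilon.
#'
#' @param model a [csp_fit()] result.
#' @param ts a [trial_set()] with the same channel count.
#' @param m number of filters kept from each end; `2 * m <= channels`.
#' @param eps variance floor for the log.
#' @return a [feature_tensor()] of `2m x 1` matrices.
#' @export
csp_transform <- function(model, ts, m = 2, eps = 1e-12) {
  stopifnot(inherits(model, "csp_model"), inherits(ts, "trial_set"))
  c <- nrow(model$filters)
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  if (2 * m > c) stop("2 * m may not exceed the channel count", call. = FALSE)
  sel <- c(seq_len(m), seq(c - m + 1, c))
  F <- model$filters[sel, , drop = FALSE]
  feats <- lapply(ts$trials, function(X) {
    Z <- F %*% X
    v <- apply(Z, 1, stats::var)
    ratio <- if (sum(v) > 0) v / sum(v) else rep(0, length(v))
    matrix(log(ratio + eps), ncol = 1)
  })
  feature_tensor(feats, ts$labels, feature_names = "log_var")
}

#' Rank channels by their weight in the extreme CSP filters
#'
#' Channels are scored by the maximum absolute coefficient they receive
#' across the two extreme filters (the most class-1- and most
#' class-2-discriminative); ties go to the lower channel index.
#'
#' @param model a [csp_fit()] result.
#' @param n_ch how many channels to keep.
#' @return integer vector of channel indices in rank order.
#' @export
select_channels <- function(model, n_ch) {
  stopifnot(inherits(model, "csp_model"))
  c <- ncol(model$filters)
  if (n_ch < 1 || n_ch > c) stop("`n_ch` must be between 1 and the channel count", call. = FALSE)
  extremes <- model$filters[c(1, nrow(model$filters)), , drop = FALSE]
  score <- apply(abs(extremes), 2, max)
  order(-score, seq_len(c))[seq_len(n_ch)]
}

#' Time-domain-parameter features
#'
#' Hjorth-style features: per channel, the log variance of the signal and
#' of its successive derivatives (first differences scaled by the sampling
#' rate), orders `0..K`.  A floor `eps` guards constant signals.
#'
#' @param ts a [trial_set()].
#' @param K highest derivative order (`K = 2` gives activity-style,
#'   mobility-style and complexity-style columns).
#' @param eps variance floor.
#' @return a [feature_tensor()] of `channels x (K + 1)` matrices.
#' @export
tdp_features <- function(ts, K = 2, eps = 1e-12) {
  stopifnot(inherits(ts, "trial_set"), K >= 0)
  T <- ncol(ts$trials[[1]])
  if (T <= K + 1) stop("trial length must exceed K + 1", call. = FALSE)
  feats <- lapply(ts$trials, function(X) {
    out <- matrix(0, nrow(X), K + 1)
    D <- X
    for (k in 0:K) {
      out[, k + 1] <- log(apply(D, 1, stats::var) + eps)
      if (k < K) D <- t(diff(t(D))) * ts$fs
    }
    out
  })
  feature_tensor(feats, ts$labels,
                 feature_names = paste0("log_var_d", 0:K))
}

.mi_bits <- function(x, y, n_bins) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) return(0)
  xb <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  joint <- table(xb, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Rank features by mutual information with the class label
#'
#' Estimates the mutual information between each flattened feature (one
#' index per entry of the trial feature matrix) and the label with an
#' equal-width histogram of `ceiling(sqrt(n))` bins, and returns the `k`
#' highest-scoring feature indices.  This is the information-based band /
#' feature selection stage of a filter-bank CSP pipeline.
#'
#' @param ft a [feature_tensor()] with at least two classes.
#' @param k number of feature indices to return.
#' @return integer vector of column indices into [flatten_features()],
#'   in decreasing order of estimated mutual information.
#' @export
fbcsp_select <- function(ft, k) {
  stopifnot(inherits(ft, "feature_tensor"))
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  X <- flatten_features(ft)
  if (k > ncol(X)) stop("`k` exceeds the number of features", call. = FALSE)
  if (length(unique(ft$labels)) < 2) stop("need at least two classes", call. = FALSE)
  n_bins <- ceiling(sqrt(nrow(X)))
  mi <- apply(X, 2, .mi_bits, y = ft$labels, n_bins = n_bins)
  order(-mi, seq_len(ncol(X)))[seq_len(k)]
}

#' Keep a subset of flattened feature indices
#'
#' Companion to [fbcsp_select()]: restricts every trial's feature matrix to
#' the chosen flattened indices, returned as single-column matrices.
#'
#' @param ft a [feature_tensor()].
#' @param idx flattened feature indices to keep.
#' @return a [feature_tensor()].
#' @export
subset_features <- function(ft, idx) {
  stopifnot(inherits(ft, "feature_tensor"))
  feats <- lapply(ft$features, function(X) matrix(as.vector(X)[idx], ncol = 1))
  feature_tensor(feats, ft$labels)
}
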