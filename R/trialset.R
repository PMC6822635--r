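#' Labeled collections of matrix-variate EEG trials
#'
#' A `trial_set` holds a list of equal-shape channels-by-time matrices, one
#' class label per trial, the sampling rate, and channel names.  It is the
#' universal input to the preprocessing and classification stages.  A
#' `feature_tensor` is the analogous container after feature extraction:
#' equal-shape feature matrices (rows are channels or spatial components,
#' columns are feature indices) aligned with the same labels.
#'
#' @name trial-containers
NULL

#' Construct a trial set
#'
#' @param trials list of numeric matrices, all of identical shape
#'   (channels x time samples).
#' @param labels vector of class identifiers, one per trial.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector of channel names; defaults
#'   to `ch01, ch02, ...`.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, fs, channel_names = NULL) {
  if (!is.list(trials)) stop("`trials` must be a list of matrices", call. = FALSE)
  trials <- lapply(trials, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  n <- length(trials)
  if (length(labels) != n)
    stop("length(labels) must equal the number of trials", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (n > 0) {
    dims <- vapply(trials, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all trials must share the same channels x time shape", call. = FALSE)
    bad <- which(vapply(trials, function(x) any(!is.finite(x)), logical(1)))
    if (length(bad))
      stop("non-finite entries in trial(s) ", paste(bad, collapse = ", "), call. = FALSE)
    c <- dims[1, 1]
  } else {
    c <- 0L
  }
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(c))
  if (length(channel_names) != c)
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  structure(
    list(trials = trials, labels = labels, fs = fs,
         channel_names = as.character(channel_names)),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  n <- length(x$trials)
  if (n) {
    d <- dim(x$trials[[1]])
    cat(sprintf("trial_set: %d trials of %d channels x %d samples @ %g Hz\n",
                n, d[1], d[2], x$fs))
  } else {
    cat(sprintf("trial_set: empty @ %g Hz\n", x$fs))
  }
  if (n) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Subset a trial set by trial index
#'
#' @param x a `trial_set`.
#' @param i integer or logical index over trials.
#' @param ... unused.
#' @export
`[.trial_set` <- function(x, i, ...) {
  trial_set(x$trials[i], x$labels[i], x$fs, x$channel_names)
}

#' Construct a feature tensor
#'
#' @param features list of equal-shape numeric matrices (one per trial).
#' @param labels vector of class identifiers aligned with `features`.
#' @param feature_names optional column labels.
#' @return An object of class `feature_tensor`.
#' @export
feature_tensor <- function(features, labels, feature_names = NULL) {
  if (!is.list(features)) stop("`features` must be a list of matrices", call. = FALSE)
  features <- lapply(features, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  n <- length(features)
  if (length(labels) != n)
    stop("length(labels) must equal the number of feature matrices", call. = FALSE)
  if (n > 0) {
    dims <- vapply(features, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all feature matrices must share the same shape", call. = FALSE)
    q <- dims[2, 1]
  } else {
    q <- 0L
  }
  if (!is.null(feature_names) && length(feature_names) != q)
    stop("`feature_names` must have one entry per feature column", call. = FALSE)
  structure(
    list(features = features, labels = labels, feature_names = feature_names),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  n <- length(x$features)
  if (n) {
    d <- dim(x$features[[1]])
    cat(sprintf("feature_tensor: %d trials, %d x %d feature matrices\n", n, d[1], d[2]))
  } else cat("feature_tensor: empty\n")
  invisible(x)
}

#' @export
length.feature_tensor <- function(x) length(x$features)

#' @export
`[.feature_tensor` <- function(x, i, ...) {
  feature_tensor(x$features[i], x$labels[i], x$feature_names)
}

#' Stack feature matrices as rows of a flat design matrix
#'
#' Vectorizes each trial's feature matrix (column-major) into one row.
#' @param ft a `feature_tensor`.
#' @return numeric matrix, trials x (p*q).
#' @export
flatten_features <- function(ft) {
  stopifnot(inherits(ft, "feature_tensor"))
  if (!length(ft$features)) return(matrix(0, 0, 0))
  t(vapply(ft$features, as.vector, numeric(length(ft$features[[1]]))))
}
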