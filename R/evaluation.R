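#' Chance-corrected accuracy (Cohen's kappa, balanced-class form)
#'
#' For a k-class problem with balanced classes the chance level is
#' `p_o = 1/k`, and `kappa = (accuracy - p_o) / (1 - p_o)`.
#'
#' @param accuracy observed accuracy in `[0, 1]`.
#' @param n_classes number of classes, >= 2.
#' @return kappa value (1 at perfect accuracy, 0 at chance).
#' @examples
#' cohen_kappa(0.91, 4)  # 0.88
#' @export
cohen_kappa <- function(accuracy, n_classes) {
  if (n_classes < 2) stop("`n_classes` must be at least 2", call. = FALSE)
  if (any(accuracy < 0 | accuracy > 1)) stop("`accuracy` must lie in [0, 1]", call. = FALSE)
  p_o <- 1 / n_classes
  (accuracy - p_o) / (1 - p_o)
}

#' Per-class and macro precision, recall and F-measure
#'
#' Rows of the confusion matrix are true classes, columns predictions.
#' Zero denominators (a class never predicted, or absent) yield 0 and are
#' flagged in `degenerate`.
#'
#' @param confusion square matrix of nonnegative counts.
#' @return list with `per_class` (data.frame of precision/recall/F1),
#'   `macro` (unweighted means), `accuracy`, and `degenerate` flags.
#' @export
precision_recall_f <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stop("`confusion` must be a square matrix of nonnegative counts", call. = FALSE)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(confusion)))
  list(
    per_class = data.frame(class = cls, precision = precision,
                           recall = recall, f1 = f1, row.names = NULL),
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    accuracy = safe_div(sum(tp), sum(confusion)),
    degenerate = cls[(tp + fp) == 0 | (tp + fn) == 0]
  )
}

#' Stratified k-fold partition
#'
#' Shuffles each class independently (deterministic given `seed`) and
#' deals its members round-robin across folds, so per-fold class
#' proportions are within one sample of the global proportions and the
#' folds form an exact partition of the indices.
#'
#' @param labels class labels, one per sample.
#' @param k number of folds, >= 2.
#' @param seed integer seed.
#' @return list of `k` integer vectors of validation indices.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > n) stop("`k` may not exceed the number of samples", call. = FALSE)
  counts <- table(labels)
  if (any(counts < k))
    warning("class(es) with fewer than k members: ",
            paste(names(counts)[counts < k], collapse = ", "),
            "; folds will be unbalanced for them")
  set.seed(.derive_seed(seed, 11L))
  folds <- vector("list", k)
  offset <- 0L
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    offset <- (offset + length(idx)) %% k
  }
  lapply(folds, sort)
}

#' All unordered class pairs
#'
#' Turns a k-class problem into its `choose(k, 2)` binary sub-problems,
#' in lexicographic order.
#'
#' @param classes vector of class labels (duplicates ignored).
#' @return list of length-2 vectors.
#' @export
pairwise_tasks <- function(classes) {
  u <- sort(unique(classes))
  if (length(u) < 2) stop("need at least two classes", call. = FALSE)
  pairs <- utils::combn(u, 2, simplify = FALSE)
  pairs
}

.confusion_matrix <- function(truth, predicted, classes) {
  tab <- table(factor(as.character(truth), levels = as.character(classes)),
               factor(as.character(predicted), levels = as.character(classes)))
  M <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(as.character(classes), as.character(classes)))
  M
}

#' Cross-validated evaluation of a feature + classifier pipeline
#'
#' Runs stratified k-fold cross-validation of a configurable pipeline.
#' All fitting (feature extraction, decomposition, classifier) happens on
#' the training folds only; the held-out fold is transformed with the
#' fitted stages and scored.  The configuration is a list with entries:
#'
#' * `features`: `"none"` (input is already a `feature_tensor`), `"csp"`,
#'   `"tdp"`, or `"fbcsp"` (trial-set input).
#' * `classifier`: `"svm"` or `"rsmm"`.
#' * optional `decomposition`: `"orpca"` or `"rjspca"` applied to the
#'   feature matrices, with `k` components.
#' * stage parameters: `m` (CSP filters per end), `K` (derivative order),
#'   `n_select` (features kept by mutual information), `k` (components),
#'   `lambda_a`, `lambda_b`, `gamma`, `tau`, `C`.
#'
#' @param data a [trial_set()] or [feature_tensor()].
#' @param config pipeline configuration list (see details).
#' @param k number of folds.
#' @param seed fold seed.
#' @return list of class `eval_report`: `accuracy`, `p_o`, `kappa`,
#'   `confusion`, `per_class`, `macro`, `fold_results`, `seed`.
#' @export
cross_validate <- function(data, config = list(features = "none", classifier = "svm"),
                           k = 5, seed = 1L) {
  labels <- data$labels
  classes <- sort(unique(labels))
  feat_method <- config$features %||% "none"
  clf_method <- config$classifier %||% "svm"
  if (!feat_method %in% c("none", "csp", "tdp", "fbcsp"))
    stop("unknown feature method: ", feat_method, call. = FALSE)
  if (!clf_method %in% c("svm", "rsmm"))
    stop("unknown classifier: ", clf_method, call. = FALSE)
  if (!is.null(config$decomposition) && !config$decomposition %in% c("orpca", "rjspca"))
    stop("unknown decomposition: ", config$decomposition, call. = FALSE)
  folds <- stratified_kfold(labels, k, seed)
  n <- length(labels)
  fold_results <- vector("list", k)
  predicted <- rep(NA_character_, n)
  for (f in seq_len(k)) {
    val <- folds[[f]]
    tr <- setdiff(seq_len(n), val)
    fitted <- .fit_pipeline(data[tr], config, feat_method, clf_method)
    pred <- .predict_pipeline(fitted, data[val])
    predicted[val] <- as.character(pred)
    fold_results[[f]] <- list(
      fold = f, indices = val,
      accuracy = mean(as.character(pred) == as.character(labels[val])),
      n = length(val)
    )
  }
  confusion <- .confusion_matrix(labels, predicted, classes)
  prf <- precision_recall_f(confusion)
  accuracy <- prf$accuracy
  structure(
    list(accuracy = accuracy, p_o = 1 / length(classes),
         kappa = cohen_kappa(accuracy, length(classes)),
         confusion = confusion, per_class = prf$per_class, macro = prf$macro,
         degenerate = prf$degenerate,
         fold_results = fold_results, k = k, seed = seed, config = config),
    class = "eval_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fit_pipeline <- function(train, config, feat_method, clf_method) {
  state <- list(config = config, feat_method = feat_method, clf_method = clf_method)
  ft <- switch(feat_method,
    none = {
      stopifnot(inherits(train, "feature_tensor"))
      train
    },
    csp = {
      state$csp <- csp_fit(train)
      csp_transform(state$csp, train, m = config$m %||% 2)
    },
    tdp = tdp_features(train, K = config$K %||% 2),
    fbcsp = {
      bands <- config$bands %||% default_filterbank()
      state$bank <- bands
      banded <- bandpass_filterbank(train, bands)
      state$csp <- lapply(banded, csp_fit)
      ft_bands <- Map(function(m, b) csp_transform(m, b, m = config$m %||% 2),
                      state$csp, banded)
      stacked <- feature_tensor(
        lapply(seq_along(train$labels), function(i)
          do.call(cbind, lapply(ft_bands, function(fb) fb$features[[i]]))),
        train$labels)
      state$selected <- fbcsp_select(stacked, config$n_select %||%
                                       min(8, length(as.vector(stacked$features[[1]]))))
      subset_features(stacked, state$selected)
    }
  )
  if (!is.null(config$decomposition)) {
    kc <- config$k %||% min(2, ncol(ft$features[[1]]))
    state$decomp <- switch(config$decomposition,
      orpca = orpca_fit(ft, kc, lambda_a = config$lambda_a %||% 0.1),
      rjspca = rjspca_fit(ft, kc, lambda_a = config$lambda_a %||% 0.1,
                          lambda_b = config$lambda_b %||% 0.1))
    ft <- project_features(state$decomp, ft)
  }
  state$model <- switch(clf_method,
    svm = svm_baseline_fit(ft, C = config$C %||% 1),
    rsmm = rsmm_fit_multiclass(ft, gamma = config$gamma %||% 0.1,
                               tau = config$tau %||% 0.1, C = config$C %||% 1))
  state
}

.predict_pipeline <- function(state, newdata) {
  config <- state$config
  ft <- switch(state$feat_method,
    none = newdata,
    csp = csp_transform(state$csp, newdata, m = config$m %||% 2),
    tdp = tdp_features(newdata, K = config$K %||% 2),
    fbcsp = {
      banded <- bandpass_filterbank(newdata, state$bank)
      ft_bands <- Map(function(m, b) csp_transform(m, b, m = config$m %||% 2),
                      state$csp, banded)
      stacked <- feature_tensor(
        lapply(seq_along(newdata$labels), function(i)
          do.call(cbind, lapply(ft_bands, function(fb) fb$features[[i]]))),
        newdata$labels)
      subset_features(stacked, state$selected)
    })
  if (!is.null(state$decomp)) ft <- project_features(state$decomp, ft)
  smm_predict(state$model, ft)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("accuracy %.4f   kappa %.4f   (chance %.4f)\n",
              x$accuracy, x$kappa, x$p_o))
  cat(sprintf("macro precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON text
#'
#' @param report an `eval_report`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_eval_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(
    accuracy = report$accuracy, p_o = report$p_o, kappa = report$kappa,
    macro = as.list(report$macro),
    per_class = report$per_class,
    confusion = unname(apply(report$confusion, 1, as.list)),
    classes = rownames(report$confusion),
    folds = lapply(report$fold_results, function(f)
      list(fold = f$fold, accuracy = f$accuracy, n = f$n)),
    k = report$k, seed = report$seed
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}
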