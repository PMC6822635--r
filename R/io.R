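#' Plain-text trial archives
#'
#' The package's on-disk standard is a directory archive: a JSON manifest
#' (`manifest.json` with format version, kind, sampling rate, channel
#' names, labels, trial count and shape) plus one whitespace-delimited
#' numeric text file per trial (`trial_0001.txt`, rows are channels).
#' Both [trial_set()] and [feature_tensor()] objects round-trip through
#' it; numbers are written with 17 significant digits, so text round
#' trips are exact to double precision.
#'
#' @name trial-archives
NULL

.ARCHIVE_VERSION <- "1.0"

#' Write a trial set or feature tensor to a directory archive
#'
#' @param x a [trial_set()] or [feature_tensor()].
#' @param path directory to create (contents are overwritten).
#' @return `path`, invisibly.
#' @export
write_archive <- function(x, path) {
  if (!inherits(x, "trial_set") && !inherits(x, "feature_tensor"))
    stop("`x` must be a trial_set or feature_tensor", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create archive directory: ", path, call. = FALSE)
  is_trials <- inherits(x, "trial_set")
  mats <- if (is_trials) x$trials else x$features
  shape <- if (length(mats)) dim(mats[[1]]) else c(0L, 0L)
  manifest <- list(
    format_version = .ARCHIVE_VERSION,
    kind = if (is_trials) "trials" else "features",
    n_trials = length(mats),
    shape = as.integer(shape),
    labels = x$labels
  )
  if (is_trials) {
    manifest$fs <- x$fs
    manifest$channel_names <- x$channel_names
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(path, "manifest.json"))
  for (i in seq_along(mats)) {
    lines <- apply(mats[[i]], 1, function(row)
      paste(formatC(row, digits = 17, format = "g"), collapse = " "))
    writeLines(lines, file.path(path, sprintf("trial_%04d.txt", i)))
  }
  invisible(path)
}

#' Read a directory archive back into memory
#'
#' Validation problems (missing payload files, shape mismatches) are
#' collected and reported together, naming the offending trials.
#'
#' @param path archive directory written by [write_archive()].
#' @return a [trial_set()] or [feature_tensor()], per the manifest `kind`.
#' @export
read_archive <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop("not a trial archive: missing manifest at ", mf_path, call. = FALSE)
  manifest <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE)
  if (is.null(manifest$format_version))
    stop("manifest has no format version", call. = FALSE)
  n <- manifest$n_trials
  shape <- as.integer(manifest$shape)
  problems <- character(0)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    f <- file.path(path, sprintf("trial_%04d.txt", i))
    if (!file.exists(f)) {
      problems <- c(problems, sprintf("trial %d: payload file missing", i))
      next
    }
    rows <- strsplit(trimws(readLines(f)), "[[:space:]]+")
    M <- tryCatch(do.call(rbind, lapply(rows, as.numeric)),
                  warning = function(w) NULL, error = function(e) NULL)
    if (is.null(M) || is.null(dim(M)) ||
        nrow(M) != shape[1] || ncol(M) != shape[2] || any(!is.finite(M))) {
      problems <- c(problems, sprintf(
        "trial %d: expected %d x %d numeric matrix", i, shape[1], shape[2]))
      next
    }
    mats[[i]] <- M
  }
  if (length(problems))
    stop("invalid archive at ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  if (length(manifest$labels) != n)
    stop("manifest label count does not match trial count", call. = FALSE)
  if (identical(manifest$kind, "trials")) {
    trial_set(mats, manifest$labels, manifest$fs, manifest$channel_names)
  } else {
    feature_tensor(mats, manifest$labels)
  }
}

#' Save a fitted model as JSON text
#'
#' Works for the decomposition models (`loadings_model`,
#' `two_d_projection`, `low_rank_sparse`) and for `smm_model`; matrices
#' are stored as nested arrays at full precision.
#'
#' @param model a fitted model object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("loadings_model", "two_d_projection", "low_rank_sparse", "smm_model"))
    stop("unsupported model class: ", cls, call. = FALSE)
  payload <- unclass(model)
  payload$.class <- cls
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Load a model saved by [write_model()]
#'
#' @param path file written by [write_model()].
#' @return the model object with its original class.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (cls == "smm_model" && is.array(obj$W))
    obj$W <- lapply(seq_len(dim(obj$W)[1]), function(i) obj$W[i, , ])
  structure(obj, class = cls)
}
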