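#' Synthetic matrix-variate EEG trials
#'
#' The generators emulate the statistical structure that motor-imagery
#' recordings present to the pipeline: class-dependent spatial covariance,
#' band-limited rhythms mixed through class-specific spatial patterns,
#' an optional low-rank background, sparse artifact spikes, and a
#' controllable fraction of gross-amplitude outlier trials.  They make
#' every stage testable without external recordings.
#'
#' @name synthetic-trials
NULL

.derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(offset)) %% 2147483629)
}

#' Diagonal-dominant class spatial covariances
#'
#' Builds one SPD covariance per class: unit variance everywhere, with a
#' disjoint block of channels boosted by `strength` for each class, mild
#' uniform channel correlation `rho`.  This is the swap construction under
#' which CSP has a known discriminative direction.
#'
#' @param channels number of channels.
#' @param n_classes number of classes (needs `n_classes` disjoint blocks).
#' @param strength variance boost of each class's channel block.
#' @param rho baseline inter-channel correlation.
#' @return list of `channels x channels` SPD matrices.
#' @export
class_spatial_covs <- function(channels, n_classes = 2, strength = 4, rho = 0.1) {
  stopifnot(channels >= n_classes, strength > 0, rho >= 0, rho < 1)
  base <- matrix(rho, channels, channels)
  diag(base) <- 1
  block <- floor(channels / n_classes)
  lapply(seq_len(n_classes), function(k) {
    S <- base
    idx <- ((k - 1) * block + 1):(k * block)
    diag(S)[idx] <- strength
    S
  })
}

#' Specification of a synthetic trial set
#'
#' Defaults mirror a desk-scale motor-imagery session: 30 trials per class,
#' 8 channels, 2-second trials at 250 Hz, two classes with swapped
#' dominant-channel covariances, mu- and beta-band rhythms, and no
#' contamination unless requested.
#'
#' @param n_trials trials per class.
#' @param channels number of channels.
#' @param samples time samples per trial.
#' @param fs sampling rate in Hz.
#' @param class_covs list of SPD spatial covariances, one per class.
#' @param rhythm_bands list of `(low, high)` Hz pairs, one per class, or
#'   `NULL` for no oscillatory component.
#' @param rhythm_amp amplitude of the class rhythm.
#' @param background_rank rank of the shared low-rank background (0 = none).
#' @param artifact_density Bernoulli density of sparse spike artifacts.
#' @param artifact_amp amplitude of spike artifacts.
#' @param outlier_fraction fraction of trials scaled into outliers, in [0,1).
#' @param outlier_scale multiplicative amplitude of outlier trials.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_trials = 30, channels = 8, samples = 500, fs = 250,
                           class_covs = class_spatial_covs(channels, 2),
                           rhythm_bands = list(c(9, 13), c(19, 25)),
                           rhythm_amp = 1,
                           background_rank = 0,
                           artifact_density = 0, artifact_amp = 10,
                           outlier_fraction = 0, outlier_scale = 10,
                           seed = 1L) {
  n_classes <- length(class_covs)
  stopifnot(n_classes >= 1, n_trials >= 1, samples >= 2, fs > 0,
            background_rank >= 0,
            artifact_density >= 0, artifact_density <= 1,
            outlier_fraction >= 0, outlier_fraction < 1)
  for (S in class_covs) {
    S <- as.matrix(S)
    if (nrow(S) != channels || ncol(S) != channels)
      stop("each class covariance must be channels x channels", call. = FALSE)
    if (max(abs(S - t(S))) > 1e-8 || min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("class covariances must be symmetric positive definite", call. = FALSE)
  }
  if (!is.null(rhythm_bands)) {
    stopifnot(length(rhythm_bands) == n_classes)
    for (b in rhythm_bands) stopifnot(length(b) == 2, b[1] > 0, b[1] < b[2], b[2] < fs / 2)
  }
  structure(
    list(n_trials = n_trials, channels = channels, samples = samples, fs = fs,
         class_covs = lapply(class_covs, as.matrix),
         rhythm_bands = rhythm_bands, rhythm_amp = rhythm_amp,
         background_rank = background_rank,
         artifact_density = artifact_density, artifact_amp = artifact_amp,
         outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

.sqrtm_spd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic trial set
#'
#' Each trial is spatially colored noise `Sigma_c^{1/2} E` (`E` iid standard
#' normal) plus, optionally, a band-limited sinusoidal rhythm mixed through
#' a class-specific spatial pattern, a low-rank background, and sparse
#' spike artifacts.  Outlier trials are whole-trial amplitude-scaled.
#' Per-trial sub-seeds are derived by fixed offsets from `spec$seed`, so
#' increasing `n_trials` does not perturb earlier trials.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `trials` (a [trial_set()]), `outliers`
#'   (logical flags per trial), and `class_covs` (the ground truth).
#' @export
gen_trials <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_classes <- length(spec$class_covs)
  c <- spec$channels; T <- spec$samples
  roots <- lapply(spec$class_covs, .sqrtm_spd)

  # class-level structure drawn once from the base seed
  set.seed(.derive_seed(spec$seed, 0))
  patterns <- replicate(n_classes, {
    v <- rnorm(c); v / sqrt(sum(v^2))
  }, simplify = FALSE)
  if (spec$background_rank > 0) {
    U <- matrix(rnorm(c * spec$background_rank), c)
  } else U <- NULL

  tt <- seq_len(T) / spec$fs
  trials <- vector("list", n_classes * spec$n_trials)
  labels <- integer(length(trials))
  outliers <- logical(length(trials))
  idx <- 0L
  for (k in seq_len(n_classes)) {
    for (i in seq_len(spec$n_trials)) {
      idx <- idx + 1L
      set.seed(.derive_seed(spec$seed, (k - 1L) * 1000000L + i))
      X <- roots[[k]] %*% matrix(rnorm(c * T), c, T)
      if (!is.null(spec$rhythm_bands)) {
        band <- spec$rhythm_bands[[k]]
        f <- runif(1, band[1], band[2])
        phase <- runif(1, 0, 2 * pi)
        s <- sin(2 * pi * f * tt + phase)
        X <- X + spec$rhythm_amp * patterns[[k]] %*% t(s)
      }
      if (!is.null(U)) {
        V <- matrix(rnorm(T * spec$background_rank), T)
        X <- X + (U %*% t(V)) / sqrt(spec$background_rank * T)
      }
      if (spec$artifact_density > 0) {
        mask <- matrix(runif(c * T) < spec$artifact_density, c, T)
        X[mask] <- X[mask] + spec$artifact_amp * sample(c(-1, 1), sum(mask), replace = TRUE)
      }
      is_out <- spec$outlier_fraction > 0 && runif(1) < spec$outlier_fraction
      if (is_out) X <- X * spec$outlier_scale
      trials[[idx]] <- X
      labels[idx] <- k
      outliers[idx] <- is_out
    }
  }
  list(
    trials = trial_set(trials, labels, spec$fs),
    outliers = outliers,
    class_covs = spec$class_covs
  )
}

#' Low-rank plus sparse test matrix
#'
#' `L0 = U V'` with iid standard normal factors of width `rank`; `S0` has
#' Bernoulli(`density`) support with entries `+/- amplitude`; `X = L0 + S0`.
#'
#' @param m,n matrix dimensions.
#' @param rank rank of the low-rank part (`0` gives `L0 = 0`).
#' @param density sparse support density in `[0, 1]`.
#' @param amplitude magnitude of sparse entries.
#' @param seed integer seed.
#' @return list with `X`, `L0`, `S0`.
#' @export
gen_lowrank_sparse <- function(m, n, rank, density, amplitude = 10, seed = 1L) {
  stopifnot(rank <= min(m, n), density >= 0, density <= 1)
  set.seed(.derive_seed(seed, 31L))
  if (rank > 0) {
    L0 <- matrix(rnorm(m * rank), m) %*% t(matrix(rnorm(n * rank), n))
  } else {
    L0 <- matrix(0, m, n)
  }
  S0 <- matrix(0, m, n)
  if (density > 0) {
    mask <- matrix(runif(m * n) < density, m, n)
    S0[mask] <- amplitude * sample(c(-1, 1), sum(mask), replace = TRUE)
  }
  list(X = L0 + S0, L0 = L0, S0 = S0)
}

#' Feature matrix with a planted informative row support
#'
#' Informative rows carry a shared equal-weight latent factor at
#' signal-to-noise ratio `snr`; the remaining rows are pure unit noise.
#' `n_outliers` columns (samples) are replaced by gross noise at
#' `outlier_sd` times the nominal noise scale.  This is the fixture for
#' row-support recovery by the joint-sparse decompositions.
#'
#' @param p number of rows (features).
#' @param n number of columns (samples).
#' @param k_informative number of informative rows.
#' @param snr amplitude of the shared factor in the informative rows.
#' @param n_outliers number of corrupted sample columns.
#' @param outlier_sd standard deviation of the corrupted columns, in units
#'   of the nominal (unit) noise scale.
#' @param seed integer seed.
#' @return list with `X` (p x n), `support` (informative row indices),
#'   and `outlier_cols`.
#' @export
gen_row_informative <- function(p, n, k_informative, snr = 4, n_outliers = 0,
                                outlier_sd = 5, seed = 1L) {
  stopifnot(k_informative <= p, n_outliers <= n)
  set.seed(.derive_seed(seed, 57L))
  support <- seq_len(k_informative)
  z <- rnorm(n)
  w <- sample(c(-1, 1), k_informative, replace = TRUE)
  X <- matrix(rnorm(p * n), p, n)
  X[support, ] <- X[support, ] + snr * (w %*% t(z))
  out_cols <- integer(0)
  if (n_outliers > 0) {
    out_cols <- sample.int(n, n_outliers)
    X[, out_cols] <- matrix(rnorm(p * n_outliers, sd = outlier_sd), p)
  }
  list(X = X, support = support, outlier_cols = sort(out_cols))
}
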