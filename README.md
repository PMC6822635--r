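# bcimatrix

Matrix-variate feature selection and robust support matrix machines for
motor-imagery EEG classification.

Multichannel EEG trials are naturally matrices (channels × time), and
imagined-movement tasks modulate their spatial covariance structure.
Vectorizing trials before feature selection or classification destroys
the row/column correlation that carries most of the signal, and EEG is
riddled with artifacts: gross outlier trials, spikes, and non-standard
noise.  `bcimatrix` is a toolkit for people who want to classify such
matrix data without vectorizing it and without letting outliers steer
the estimates.  It provides:

* **Preprocessing** — Cochran sample sizing with finite-population
  correction `n0 = Z²p(1−p)/e²`, `n = n0/(1+(n0−1)/N)`; contiguous
  window segmentation; variance-weighted sample allocation
  `n(i) ∝ N_i √(Σ_j Var²_{ij})`; a 4–40 Hz Butterworth filter bank;
  common spatial patterns (CSP) via the generalized eigenproblem
  `Σ₁w = λ(Σ₁+Σ₂)w`; CSP channel selection; Hjorth-style
  time-domain-parameter features; mutual-information feature ranking
  (filter-bank CSP style).
* **Sparse / robust decompositions** — sparse PCA
  (`‖X−ABᵀX‖²_F + λ₁‖β_j‖² + λ₂‖β_j‖₁`), joint-sparse PCA
  (`‖X−ABᵀX‖₂,₁ + λ‖B‖₂,₁`), group-sparse PCA, two-dimensional PCA with
  ridge (`Σ_j‖X_j−X_jQPᵀ‖²_F + λ_a‖Q‖²_F`) and its row-sparse variant
  (`+ λ_b‖Q‖₂,₁`), and principal component pursuit
  (`min ‖L‖_* + λ‖S‖₁ s.t. X = L+S`).
* **Classification** — a multiclass robust support matrix machine
  minimizing `γ‖W‖₂,₁ + τ‖W‖_* + C Σ_i max(0, 1 − y_i(tr(WᵀX_i)+b))`
  by consensus ADMM (exact SMO hinge block, singular value thresholding,
  row-wise group soft threshold), plus an in-package linear SVM baseline.
* **Evaluation** — balanced-chance Cohen's kappa
  `κ = (acc − 1/k)/(1 − 1/k)`, precision/recall/F, stratified k-fold
  cross-validation, pairwise task construction (`C(4,2) = 6` binary
  problems for four motor-imagery classes), and a leak-free pipeline
  cross-validator.
* **Synthetic data, archives, CLI** — matrix-variate trial generators
  with class-dependent spatial covariance, band-limited rhythms,
  low-rank background, artifact spikes and outlier trials; a plain-text
  trial-archive format; a command-line driver
  (`simulate / features / decompose / train / evaluate`).

## Worked example

```r
library(bcimatrix)

# a synthetic two-class motor-imagery session with 10% outlier trials
spec <- synthetic_spec(n_trials = 20, channels = 8, samples = 500, seed = 42,
                       outlier_fraction = 0.1, outlier_scale = 10)
sim <- gen_trials(spec)
sim$trials
#> trial_set: 40 trials of 8 channels x 500 samples @ 250 Hz
#> classes: 1 (20), 2 (20)

csp_fit(sim$trials)
#> csp_model: 8 filters, classes 1 vs 2
#> top eigenvalues: 0.82 0.811 0.809 0.756

# CSP log-variance features + robust support matrix machine, 5-fold CV
cross_validate(sim$trials,
               config = list(features = "csp", classifier = "rsmm", m = 2),
               k = 5, seed = 42)
#> 5-fold cross-validation (seed 42)
#> accuracy 1.0000   kappa 1.0000   (chance 0.5000)
#> macro precision 1.0000  recall 1.0000  F1 1.0000
#> confusion (rows = truth):
#>    1  2
#> 1 20  0
#> 2  0 20

compute_sample_size(0.5, 2.58, 0.01, N = 4097)
#> sample size: n0 = 16641 (uncorrected), n = 3288 after finite-population correction (N = 4097)
segment_signal(4097, 4)
#> [1] 1024 1024 1024 1025
```

The CSP eigenvalue 0.82 says the top spatial filter captures 82% of the
class-1 share of variance (0.5 would be undiscriminative); the perfect
cross-validated kappa reflects the well-separated synthetic covariances.
The same pipeline is available from the shell via the installed script
(`system.file("cli", "bcimatrix", package = "bcimatrix")`).

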