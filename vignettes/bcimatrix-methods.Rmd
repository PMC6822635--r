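---
title: "Matrix-variate decompositions and robust support matrix machines: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-variate decompositions and robust support matrix machines: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcimatrix)
```

# The problem

Motor-imagery brain–computer interfaces classify short multichannel EEG
trials — matrices $X \in \mathbb{R}^{c \times T}$ of $c$ channels by $T$
time samples — into imagined-movement classes.  Two features of this data
shape every choice in the package.  First, the discriminative information
is *structural*: imagined movement modulates the spatial covariance of
band-limited rhythms, so rows and columns of $X$ are strongly correlated
and flattening trials into vectors discards exactly the structure that
separates classes.  Second, the data are *contaminated*: measurement
artifacts produce gross outlier trials and sparse spikes that dominate
any least-squares criterion.

`bcimatrix` therefore works on matrices end to end: spatial filtering and
feature extraction keep the channel structure, the dimensionality
reducers penalize whole feature rows rather than single coefficients, and
the classifier regularizes its coefficient *matrix* with norms that favor
low rank and row sparsity.

# Preprocessing

**Sample sizing.**  `compute_sample_size()` implements Cochran's formula
$n_0 = Z^2 p (1-p) / e^2$ with the finite-population correction
$n = n_0 / (1 + (n_0 - 1)/N)$.  With $p = 0.5$ (the variance-maximizing
choice when $p$ is unknown), $Z = 2.58$ (99% confidence), $e = 0.01$ and
$N = 4097$ the corrected size is 3288.  The corrected size is rounded
*up*: a conservative convention, chosen because under-sampling is the
costlier error.

**Windowing.**  EEG is non-stationary; short windows are approximately
stationary.  `segment_signal()` cuts a signal into contiguous near-equal
windows of length $\lfloor T/k \rfloor$ with the remainder appended to
the *last* window, so 4097 samples in 4 windows gives
1024/1024/1024/1025.  `allocate_samples()` distributes a sample budget
across windows proportionally to
$N_i \sqrt{\smash[b]{\sum_j \mathrm{Var}_{ij}^2}}$ — windows with more
signal variance deserve more samples.  The printed form of this rule
yields a weight, not a count; it is interpreted here as an allocation
fraction multiplied by the budget, with largest-remainder rounding so
counts sum exactly to the budget (ties broken toward lower window index).

**Filter bank and CSP.**  `bandpass_filterbank()` applies zero-phase
(forward–backward) Butterworth band-passes of order 4; the default bank
is nine 4 Hz bands spanning 4–40 Hz, the conventional grid from theta to
low gamma.  `csp_fit()` estimates per-trial covariances as
$XX^\top/\mathrm{tr}(XX^\top)$ (trace normalization makes the fit
invariant to trial amplitude), averages them per class, and solves
$\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w$ by whitening the pooled
covariance; a ridge of $10^{-8} I$ is added only if the pooled matrix is
numerically singular.  Filters are sorted by eigenvalue, so the first and
last rows are the two most discriminative; `select_channels()` ranks
channels by the largest absolute coefficient they receive in these two
extreme filters (ties to the lower index).  CSP is fit on whole trials
rather than per window: the windowing above serves stationarity of the
variance features, while spatial patterns are assumed stable within a
trial — the simplest defensible reading, noted here as an assumption.

**Features.**  `csp_transform()` returns the log of each projected
component's share of variance (the classical CSP feature), guarding
zero-variance components with $\varepsilon = 10^{-12}$.
`tdp_features()` computes Hjorth-style time-domain parameters: log
variance of the signal and of its successive first differences (scaled by
the sampling rate) up to order $K$; for a unit sinusoid at angular
frequency $\omega$ the order-1 and order-0 features differ by
$2\log\omega$, which the tests verify.  `fbcsp_select()` ranks features
by mutual information with the class label using an equal-width histogram
of $\lceil\sqrt n\rceil$ bins.  This is a single-stage simplification of
the full filter-bank CSP band-selection machinery: the histogram-MI
ranking keeps the information-theoretic criterion but drops the iterative
wrapper, a deliberate scope reduction.

# The decomposition family

All vector-variate fits take $X \in \mathbb{R}^{p\times n}$ with
*columns as samples* and return an orthonormal basis $A$ and loadings
$B$ ($A^\top A = I$); trials enter the 2D fits as matrices directly.
Every solver is initialized from classical PCA / 2D-PCA of the input and
records an `objective_trace`.

**Sparse PCA** alternates (i) per-component elastic-net problems
$\min_\beta \beta^\top (XX^\top + \lambda_1 I)\beta - 2\beta^\top XX^\top a_j
+ \lambda_{2,j}\|\beta\|_1$, solved by coordinate descent (or a
minimum-norm closed form when $\lambda_{2,j}=0$ — the pseudo-inverse
solve keeps the loadings inside the data's range space, so the
zero-penalty fit reproduces the PCA subspace exactly), and (ii) a
Procrustes update $A = UV^\top$ from the SVD of $XX^\top B$.  Both steps
decrease the objective; iteration stops when $\max|\Delta B| < 10^{-6}$
or at 200 iterations.

**Joint-sparse PCA** replaces both the loss and the penalty with
$\ell_{2,1}$ norms: the loss sums the Euclidean norms of residual
*columns* (so one gross outlier sample costs its norm, not its squared
norm), the penalty sums the norms of loading *rows* (so features are
kept or dropped jointly across components).  It is solved by iteratively
reweighted least squares with weights $1/(2\max(\|r\|, \varepsilon))$,
$\varepsilon = 10^{-6}$.  The recorded objective is the
$\varepsilon$-smoothed (Huber, centred so the smoothed norm of zero is
zero) version, which the majorize–minimize iteration provably decreases
monotonically; the raw and smoothed objectives differ by at most
$\varepsilon/2$ per term.

**Group-sparse PCA** penalizes Frobenius norms of predefined row groups
with weights $\eta_g = \sqrt{|g|}$.  The loadings step is proximal
gradient with step $1/L$, $L = 2\lambda_{\max}(XX^\top)$, whose blockwise
group soft-threshold sets entire groups *exactly* to zero; with singleton
groups and zero penalty it coincides with unpenalized sparse PCA.

**2D-PCA with ridge (and its row-sparse variant)** minimizes
$\sum_j \|X_j - X_j Q P^\top\|_F^2 + \lambda_a \|Q\|_F^2
(+ \lambda_b\|Q\|_{2,1})$ over a regression matrix $Q$ and an orthonormal
projection $P$.  Orthonormality of $P$ is imposed (via a Procrustes step)
even though the formulation does not state it: without it the
reconstruction $XQP^\top$ is scale-degenerate.  The $Q$ step is a ridge
solve, extended by an IRLS diagonal $\lambda_b D$,
$D = \mathrm{diag}(1/(2\max(\|q_i\|,\varepsilon)))$, for the row-sparse
variant; rows of $Q$ whose norm falls below $10^{-6}$ times the largest
row norm are reported as discarded features.  With both penalties zero
the alternation is a subspace iteration that reproduces the top
eigenvectors of the pooled scatter $\sum_j X_j^\top X_j$.

**Principal component pursuit** solves
$\min \|L\|_* + \lambda\|S\|_1$ s.t. $X = L + S$ by the inexact augmented
Lagrangian method: singular value thresholding on $L$, elementwise soft
thresholding on $S$, dual ascent, with $\mu_0 = 1.25/\|X\|_2$ increased
by 1.5 per iteration and the universal default
$\lambda = 1/\sqrt{\max(m,n)}$.  Although the narrative around this
decomposition speaks of $S$ having few nonzero *columns*, the printed
norm is the elementwise $\ell_1$, and that is what is implemented; the
entrywise model is also the one with standard exact-recovery guarantees,
which the 200×200 rank-5 / 5%-corruption test exercises.  The $\ell_0$
formulation that motivates the family is not implemented — it is
intractable and serves only as motivation — and the transposition
conventions follow the per-sample reconstruction form
$x_i \approx AB^\top x_i$ throughout.

# The robust support matrix machine

The classifier minimizes, per binary problem,
$$\gamma\|W\|_{2,1} + \tau\|W\|_* +
  C\sum_i \max\!\big(0,\, 1 - y_i(\mathrm{tr}(W^\top X_i) + b)\big),$$
with a *matrix* coefficient $W$: the nuclear norm exploits row/column
correlation (low-rank discriminative structure), the $\ell_{2,1}$ norm
drops uninformative feature rows jointly, and the offset $b$ is free.
Multiclass problems are decomposed one-vs-rest — the constraint system
decouples given per-class slacks, and prediction is
$\arg\max_j \mathrm{tr}(W_j^\top X) + b_j$ with ties to the lowest class
label.  A joint (Crammer–Singer-style) formulation was considered and
rejected: it complicates the solver without changing the per-class
geometry, and pairwise/one-vs-rest reductions are the field's norm.

**Solver.**  Consensus ADMM with three blocks sharing a consensus
variable $Z$: the hinge block is an exact proximal linear SVM solved in
the dual by SMO-style maximal-violating-pair coordinate descent (inner
KKT tolerance $10^{-8}$, warm-started across iterations; $b$ is recovered
from the free support vectors), the nuclear block is singular value
thresholding with threshold $\tau/\rho$, and the row block is the group
soft threshold with $\gamma/\rho$.  The penalty parameter starts at
$\rho = 1$ with residual balancing (doubled/halved when the primal and
dual residuals diverge by more than a decade); termination at
$\max(r, s) < 10^{-4}\max(1, \|Z\|_F)$ or 500 iterations.

**Incumbent reporting.**  ADMM is not a descent method: the objective
evaluated along its iterates oscillates around the optimum with decaying
amplitude.  The solver therefore returns the *incumbent* — the iterate
with the lowest objective seen — and `solver_trace` records the incumbent
objective, which is non-increasing by construction.  The raw primal/dual
residuals are kept in the model for convergence diagnostics, and the
structured proximal blocks of the incumbent (`W_lowrank`, `W_sparse`) are
exposed because they, not the consensus average, carry the exact low-rank
/ row-sparse structure (e.g. rank under a dominant $\tau$ is assessed on
`W_lowrank` at the $10^{-10}$ relative singular-value tolerance).

**Defaults.**  $\gamma = \tau = 0.1$, $C = 1$; nothing in the source
formulation pins these, so a small grid-search helper (`rsmm_grid()`)
over $10^{-3}..10^2$ is provided but never invoked implicitly.  With
$\gamma = \tau = 0$ the problem degenerates to pure hinge minimization,
which on separable data sign-matches the SVM baseline; the baseline
itself (`svm_baseline_fit()`) is the same SMO solver applied to
$\tfrac12\|W\|_F^2 + C\sum\xi$ and is the vectorized reference that the
trace identity $\mathrm{tr}(W^\top X) = \mathrm{vec}(W)^\top\mathrm{vec}(X)$
makes exactly equivalent to a matrix-form SVM.

# Evaluation

Cohen's kappa uses the balanced-class chance level $p_o = 1/k$, i.e.
$\kappa = (\mathrm{acc} - 1/k)/(1 - 1/k)$ — a deliberate divergence from
the marginal-product form of the general definition, matching the
balanced designs the package targets.  Precision/recall/F are macro
averaged (each class weighted equally); zero denominators yield 0 and are
flagged rather than propagated as `NaN`.  `stratified_kfold()` deals each
class round-robin after a seeded shuffle, giving exact partitions with
per-fold class counts within one of proportional; stratification is an
addition over plain k-fold, adopted to stabilize small-class folds.
`cross_validate()` fits *every* stage — spatial filters, feature
selection, decomposition, classifier — on the training folds only; the
test suite includes a memorization detector (pure-noise features that an
overfitting classifier can memorize in-sample) confirming that held-out
accuracy stays at chance.  `pairwise_tasks()` enumerates the
$\binom{k}{2}$ binary problems (6 for four classes) used to decompose
multiclass experiments.  No significance test between classifiers is
provided: the upstream description of such a test is unspecified, and
guessing one would be worse than omitting it.

# Synthetic data: what it does and does not emulate

`gen_trials()` draws each trial as $\Sigma_c^{1/2}E$ (iid normal $E$,
class-dependent SPD spatial covariance $\Sigma_c$), optionally adds a
band-limited sinusoidal rhythm mixed through a class-specific spatial
pattern, a shared low-rank background, sparse spike artifacts, and scales
a Bernoulli fraction of trials by a gross amplitude factor (the outlier
model: whole-trial artifacts, matching the "outlier trial" narrative;
entrywise spikes are available separately).  Per-trial sub-seeds are
derived from the base seed by fixed offsets, so enlarging a session never
perturbs existing trials, and every generator is a pure function of
(spec, seed).  Defaults describe a desk-scale session: 30 trials per
class, 8 channels, 2 s at 250 Hz, two classes with swapped
dominant-channel covariance blocks and mu/beta rhythms.

What this emulates: class-dependent spatial covariance (what CSP and the
classifiers exploit), band-limited oscillations (what the filter bank
isolates), low-rank-plus-sparse structure (what PCP separates), and
heavy-tailed trial contamination (what the robust losses resist).  What
it does not: volume-conduction forward models, realistic EOG/EMG artifact
waveforms, non-stationarity across a session, inter-subject variability.
Passing tests on this generator therefore demonstrate algorithmic
correctness and the claimed robustness *mechanisms*, not performance on
real recordings.

`gen_row_informative()` plants an equal-magnitude random-sign shared
factor in a few feature rows and replaces a fraction of sample columns
with gross noise at `outlier_sd` (default 5) times the nominal scale.
The default is deliberate: corruption at that level is gross enough to
derail least-squares subspace ranking, yet below the breakdown point at
which a single corrupted column's scatter exceeds the entire planted
signal and *no* rank-limited method — robust or not — can recover the
support.  The robustness claims of these estimators concern the former
regime, not the latter.

# The robustness benchmarks

`support_recovery_benchmark()` fixes the comparison protocol: 20
features, 50 samples, 2 planted rows at snr 3, 10% outlier columns, 3
components, and *matched sparsifying penalties* — lasso weight 20 for
sparse PCA, $\ell_{2,1}$ weight 20 for joint-sparse PCA, row penalty 10
for the 2D variant (samples presented as $1\times p$ trials); estimated
support is the top-2 rows by loading norm, scored by F1.  Matching the
penalty *strength* matters: the 2D variant keeps the squared Frobenius
loss, so on shared data its scatter matrix is identical to sparse PCA's
and the two differ only through their penalties.  Its advantage —
entrywise lasso scatters support decisions independently across
components, while the joint row penalty makes one decision per feature —
only expresses itself once the penalties are strong enough to sparsify.
The joint-sparse fit differs more fundamentally (its column-robust loss
down-weights outlier samples) and dominates throughout.

`classifier_robustness_benchmark()` probes the regime where matrix
regularization matters: 24 channels with a single discriminative channel
per class, only 8 training trials per class, 10% outlier trials scaled
×10, time-domain-parameter features, and scoring on an independent
30-trial-per-class contaminated session.  The comparison is
$\mathrm{acc}_{\mathrm{rsmm}} \ge \mathrm{acc}_{\mathrm{svm}}$ on the
20-replicate average; the advantage is small and consistent in this
regime, and amplitude outliers alone are nearly harmless to any linear
margin classifier (a scaled correctly-labelled point moves *away* from
the boundary), which is why the benchmark pairs contamination with a
small-sample, many-noise-channel design.

# Numerical choices, degenerate inputs, problem sizes

* SVD-based steps treat singular values below $10^{-10}$ of the largest
  as zero; `prox_row_l21` returns zero rows unchanged (a guard, not an
  $\varepsilon$).
* Zero-variance trials yield floor features (`log` of $\varepsilon$)
  rather than errors; all-zero variance allocations and single-class CSP
  inputs are errors.
* Ties everywhere break toward the lower index (channel ranking, feature
  ranking, largest-remainder rounding, class prediction).
* Archives store doubles at 17 significant digits, so text round trips
  are bit-exact; model files are JSON with full-precision matrices.
* Test and acceptance problem sizes (tens of trials, ≤ 24 channels,
  200×200 for pursuit, 20-replicate benchmarks) are chosen so the whole
  suite runs in well under a minute of compute per module while keeping
  every statistical check comfortably powered; they are stated in the
  benchmark documentation and are part of the fixed protocol, not tuning
  knobs.

# Known limitations

Band selection is single-stage MI ranking, not the full wrapper; CSP is
two-class (multiclass spatial filtering would need joint diagonalization
or one-vs-rest filter banks); the 2D decompositions' squared loss is not
robust to gross outlier *samples* (only their penalties are, as analyzed
above); no kernelized SMM, no probability calibration, no automatic
selection of the component count $k$; no GDF/EDF readers — external
recordings must be converted to the text archive format first.
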