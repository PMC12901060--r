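---
title: "Alignment dimensionality and the principal functional gradient: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment dimensionality and the principal functional gradient: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gradalign` studies a seemingly innocuous pipeline choice in functional
connectivity (FC) gradient analysis: **how many gradients are used in
orthogonal Procrustes alignment** before the aligned *principal* gradient is
carried into downstream subject-level analyses. The package implements the
full chain — FC construction, spectral gradient extraction, alignment to a
holdout group reference, alignment diagnostics, connectome fingerprinting,
motion-coupling correlation sweeps, and confound-aware nested
cross-validated prediction — together with a synthetic multi-session cohort
generator so every stage can be exercised and tested without access to
restricted fMRI repositories.

# The model and procedure

## From time series to gradients

Per subject and session, a frames × parcels BOLD matrix yields a P × P
Pearson FC matrix (`pearson_fc`). Gradients are extracted by
`extract_gradients` as the composition:

1. **Row sparsification** (`sparsify_rows`): within each row independently,
   entries strictly below the row's `sparsity` quantile are zeroed
   (default 0.9, the field's common choice). Rows are thresholded
   independently, so the intermediate matrix need not be symmetric.
2. **Affinity kernel** (`affinity`): between pairs of sparsified rows —
   Gaussian `exp(-gamma * ||x - y||^2)`, cosine similarity, normalized
   angle `1 - acos(cossim)/pi` (default), Pearson, Spearman, or a
   pass-through (`none`). The result is symmetrized exactly; for the
   spectral reductions, negative entries are clipped to 0 because both
   require non-negative weights while the correlation-type kernels can
   produce negatives.
3. **Spectral reduction**: diffusion map embedding (`dm`, default),
   PCA (`pca`), or Laplacian eigenmaps (`le`).

Diffusion map embedding uses the anisotropic normalization
`W = D^-a A D^-a` with `alpha = 0.5`, row-normalizes to a transition
operator, drops the trivial constant eigenvector, and scales eigenvector
`k` by `lambda_k / (1 - lambda_k)` (the "automatic" diffusion time). These
are the defaults of the toolboxes this pipeline mirrors; the underlying
papers rarely restate them, so they are fixed here and recorded in each
`gradient_set`'s provenance. Laplacian eigenmaps solves `L v = lambda D v`
and returns the eigenvectors of smallest nonzero eigenvalue; PCA returns
standard principal-component scores of the column-centred matrix.

Eigenvectors are sign-ambiguous, so every component is deterministically
oriented: the entry of maximum absolute value is made positive, ties broken
by lowest parcel index. Components with eigenvalue below `1e-12` are
treated as degenerate and refused. A disconnected affinity graph (possible
at extreme sparsity) raises an error suggesting a lower sparsity.

## Orthogonal Procrustes alignment

Given a subject matrix **A** (parcels × n gradients) and reference **B**,
`fit_procrustes` computes the cross-covariance `C = A'B`, its SVD
`C = U S V'`, and the orthogonal minimizer `T = U V'` of `||AT - B||_F`
(the Schönemann closed form). Deliberately there is **no centering, no
scaling, and no iterative reference update**: generalized Procrustes would
leak information across subjects and is excluded by design. Alignment to
the *holdout* reference (below) keeps subject-level analyses independent.

Diagnostics exposed by `align_to_reference`:

* **correspondence** `c = max_i |t_i1| / sum_i |t_i1|` — how dominantly a
  single unaligned gradient determines the aligned principal gradient
  (1 = one-to-one, 1/n = fully distributed);
* **trans_total / trans_pg** — sums of absolute entries of `T` (whole
  matrix / first column). These are heuristic magnitudes: for a 2 × 2
  rotation the sum of absolute entries is non-monotone in the rotation
  angle, so they are implemented as printed and documented as relative,
  exploratory descriptors;
* **w_norm** — the ℓ2 norm of the raw singular values of `C` (high when
  the two subspaces are similar);
* **theta_norm** — the ℓ2 norm of the Björck–Golub principal angles
  between the *orthonormalized* column spans (low when similar). Both are
  exposed because they answer subtly different questions; singular values
  are clipped to [0, 1] before `acos` to absorb rounding (tolerance 1e-8).

## Fingerprinting and motion metrics

`identification_accuracy` matches subjects across two sessions by the
highest Pearson correlation of their aligned principal gradients; both
lookup directions are computed and averaged (the directional values are
also reported), with ties broken toward the lowest subject index under a
warning. `differential_identifiability` is
`I_diff = (I_self - I_other) * 100`, with `I_other` averaged over all
ordered pairs of distinct subjects; an optional Fisher r-to-z transform is
applied to every correlation first (correlations at ±1 are clipped to
±(1 − 1e-7) with a warning, keeping averages finite).

Motion is summarized by Power-style framewise displacement — absolute
backward differences of three translations plus three rotations converted
at a 50 mm head radius, undefined (set to 0 and excluded from the mean) at
frame 1 — and by the typicality of functional connectivity,
`TFC = (1 + r(FC_subject, FC_group)) / 2`, computed over the vectorized
upper-triangle off-diagonal entries (the constant unit diagonal would
distort the correlation). `motion_correlation_sweep` correlates each
motion metric with each alignment diagnostic across subjects, per session
and per alignment dimensionality, applying Benjamini–Hochberg FDR per
metric pair within session across the dimensionality sweep, and flags
cells significant in *every* session.

## Prediction protocol

`nested_cv_regression` / `nested_cv_classification` implement 10-times
repeated 5-fold nested cross-validation: outer folds are reshuffled per
repeat (stratified for classification), an inner 5-fold grid search picks
hyperparameters, and the winning model is refit on the full outer-training
partition. The grids follow the common neuroimaging protocol: 50 log-spaced
ridge penalties in [1e-3, 1e4], 10 log-spaced SVM costs in [1e-4, 1e4], 10
log-spaced RBF widths in [1e-9, 1e4], random-forest depth in
{5, 10, 20, unbounded}. Regression reports the out-of-sample coefficient of
determination per outer fold; classification reports accuracy and AUC. The
summary spread is the standard deviation across the 10 repeat-level means
of fold scores.

Confound handling is CV-consistent: `fit_confound_remover` fits, per
feature column, an intercept-plus-linear model on the confounds using the
outer-training rows only, and both partitions are residualized with those
training coefficients. Features (not the target) are residualized,
following the practice cited in this literature; features are additionally
z-scored with training-partition statistics (switchable via
`cv_config(standardize = )`). Motion classification targets come from
`binarize_by_median`; values equal to the median go to the low-motion
class (the tie rule had to be fixed somewhere and ties are measure-zero
for continuous FD).

Ridge solutions are computed from one SVD of the centred design per inner
fold (all penalties at once, intercept unpenalized, penalty applied to the
standardized features), which keeps the printed penalty grid on its
standard scale. Undefined scores from empty or singleton inner folds at
very small sample sizes are excluded from grid selection; a degenerate
*outer* test partition is an error.

# The synthetic cohort generator

`generate_cohort` emulates the statistical regime the analyses assume,
with one record per subject × session:

* a **group basis**: P × K orthonormal columns with a geometric variance
  spectrum (`eigen_decay^(k-1)`, default decay 0.8 — adjacent components
  have comparable variance, which is what makes their order unstable);
* a **subject basis**: the group basis rotated in parcel space by a random
  rotation of spectral-norm angle `subject_rotation_scale` (default 0.4
  rad). Rotations are matrix exponentials of random antisymmetric
  generators normalized to unit spectral norm, so the angle scale controls
  the largest principal rotation angle exactly. The generator direction is
  partly shared across subjects and weighted by a latent age factor
  (`phenotype_model$gradient_age`), giving gradients a predictable
  age-linked component;
* **session perturbations**, applied independently per session: random
  sign flips and adjacent-component swaps (probability 0.3 per component)
  plus a component-space rotation of angle `session_rotation_scale`
  (default 0.2 rad). These live at the session level because they emulate
  the sign/order/rotation instability of *independent per-session
  eigendecompositions* — the distortion Procrustes alignment exists to
  correct. (Placing them at the subject level would make them cancel in
  within-subject comparisons, and alignment dimensionality would have no
  purchase on fingerprinting at all.) The session rotation acts within the
  subject's component span, where alignment with enough components can
  undo it; the subject rotation acts in parcel space, where it cannot —
  this asymmetry is what gives subjects a stable fingerprint;
* a **motion mechanism**: each subject draws a mean FD
  (`motion_location` ± `motion_scale`, floored at 0.01 mm, partly
  correlated with the age factor); each session gets an |AR(1)| FD trace
  rescaled to that mean (FD is 0 at frame 1 by convention). Motion feeds
  back into the connectivity structure as a component-space rotation of
  angle `motion_coupling × mean FD`, directed with weight
  `trailing_emphasis` (default 0.8) at components 2..K and otherwise
  across all components, plus a rank-1 session artifact (the FD trace
  broadcast onto a random spatial map). The trailing emphasis is one
  plausible mechanism for motion accumulating in the transformation as
  more gradients are aligned; it is a modelling choice, used only for
  qualitative trend reproduction;
* **time series**: latent signals with *exactly* unit sample covariance
  (centred, orthonormalized, rescaled), so that with zero noise the sample
  FC is a deterministic function of the session basis; the signal is
  scaled so the average per-parcel variance is 1, against white noise of
  `noise_sd` (default 0.3) — roughly a 10:1 variance ratio, a
  well-denoised regime;
* **phenotypes**: an age-like variable from the latent factor and a
  score-like variable decreasing with it, so age correlates positively
  with motion and negatively with the score, qualitatively matching
  ageing-cohort structure; magnitudes are configurable and deliberately
  not calibrated to any dataset.

The default cohort (60 subjects, 2 sessions, 100 parcels, 20 latent
components, 300 frames) is sized like a parcellated single-site study at
Schaefer-100 granularity and runs the full pipeline in seconds.

What the generator does **not** model: volumetric acquisition, hemodynamic
response, spatial autocorrelation of parcels, physiological noise,
scanner- or site-effects, realistic FD marginals, or any real dataset's
effect sizes. Tests passing on this cohort therefore show that the
*machinery* behaves as specified and that the qualitative
alignment-dimensionality phenomena are reproducible under the stated
generative assumptions — not that any particular real-data effect size
would be obtained.

# The orchestrated study

`run_full_study` executes: read cohort → FC → FD/TFC → seeded 20% holdout
split → group-average FC (Fisher-z averaging) → reference gradients →
per-subject gradient extraction → alignment sweep over the requested
dimensionalities (optionally also the reversed cumulative index sets
20..k) → identifiability sweep over all session pairs → motion-correlation
sweep with FDR → prediction scenarios (none / FD / FD + age as confounds;
age prediction never removes age). Everything is keyed by a single seed;
all tables carry full parameter provenance, and a rerun from the same
configuration is byte-identical. The reference is built exclusively from
holdout subjects, and holdout subjects never enter any analysis table.

# Numerical and design choices, collected

* Fisher z at |r| ≥ 1: clipped to ±(1 − 1e-7) with a warning, keeping
  group averaging and the z-variant identifiability total.
* FD at frame 1: undefined, stored as 0, excluded from `mean_fd` and from
  BOLD–FD correlations (fMRIPrep marks it n/a; the readers accept that).
* If a confounds file already provides `framewise_displacement`, it is
  used verbatim and the six-parameter computation is skipped.
* TFC uses the upper triangle only; the unit diagonal is constant.
* Gaussian kernel width defaults to `1/P` when unspecified.
* Reference and subject gradients use identical extraction parameters.
* SVD sign/ordering under repeated singular values follows LAPACK's
  deterministic convention; rank-deficient cross-covariances warn.
* Identification ties (measure-zero for continuous data) go to the lowest
  subject index with a warning.
* The holdout split takes `round(fraction × n)` subjects, seeded.
* The BH family for the motion sweep is per metric pair within session
  across alignment dimensionalities; the "significant across all
  sessions" flag mirrors the all-sessions rule. The family choice is
  recorded in the output so alternative groupings can be recomputed.
* "Derivative" of prediction scores = first difference over consecutive
  alignment dimensionalities (`score_derivative`).

# Problem sizes used by the test suite

Unit tests run on toy matrices (4–50 parcels). End-to-end checks use the
default 60-subject, 2-session cohort at 100 parcels for the trend
reproductions; the null BOLD–FD calibration uses 100 subjects × 400
parcels × 1200 frames (the pooled null has standard deviation
`1/sqrt(T - 3) ≈ 0.029`); Procrustes optimality is checked on 200 random
8 × 3 instances against 20,000 random orthogonal candidates and on 8 × 2
instances against a 100,000-point rotation-angle grid; prediction
calibrations use 100–200 synthetic subjects. The full suite and the
acceptance script each run in well under the package's stated budgets on a
single CPU.

# Known limitations

* The transformation-magnitude descriptors are heuristics (non-monotone in
  the underlying angle) and should be read as relative, not absolute.
* Eigenvalue-weighted Procrustes alignment — an obvious remedy for the
  equal weighting of trailing gradients — is discussed in this literature
  but not defined precisely anywhere; it is deliberately not implemented.
* Laplacian eigenmaps can behave unstably under sweeps of alignment
  dimensionality; the diffusion-map default is the recommended path.
* The generator's motion mechanism is one plausible emulation chosen for
  qualitative trend reproduction, not an estimate of any real dataset's
  motion physics.
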