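---
title: "Dynamic functional connectivity states and connectome classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity states and connectome classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## What the package computes

`dynconn` implements a complete desk-scale pipeline for comparing
structural connectivity (SC), static functional connectivity (FC) and
dynamic functional connectivity (dFC) as classifiers of clinical group
membership — the setting is a multiple-sclerosis cohort (healthy controls
vs. patients; patients with vs. without disability, split at EDSS 2), but
every stage is generic.

The stages are:

1. **Static connectivity** (`compute_fc`, `node_strength`): FC is the
   Pearson correlation of regional BOLD time courses over the full scan.
   Node strength sums a region's connections; for FC and dFC, negative
   entries are removed first (negative functional weights are not
   comparable in magnitude to positive ones under this convention); SC is
   nonnegative so both conventions coincide.
2. **Dynamic FC** (`windowed_dfc`, `cluster_states`, `select_k_elbow`,
   `state_metrics`, `subject_centroids`): tapered sliding-window
   correlation, pooled k-means clustering under the Manhattan (L1)
   distance into recurring brain states, and per-subject state summaries
   (dwell time, transition probabilities, transition count, subject
   centroids, regional dFC).
3. **Mass univariate screening** (`univariate_screen`): Welch t-tests for
   FC/dFC features, Wilcoxon rank-sum for SC, chi-squared (uncorrected)
   for categoricals, Benjamini-Hochberg control within each feature
   family, significance at corrected 0.05.  SC edges are pre-filtered to
   those nonzero in a strict majority of controls, which removes likely
   tractography false positives.
4. **Classification** (`nested_cv`): ridge-penalized logistic regression
   under repeated nested stratified 5-fold cross-validation, SMOTE
   oversampling of the minority class inside the training folds, and AUC /
   sensitivity / specificity / balanced accuracy / F1 per hold-out fold.
   Models are compared with a paired sign-flip permutation test on
   per-fold AUCs.
5. **Importance** (`aggregate_weights`, `flag_important`,
   `network_summary`): coefficients averaged over all fits, scaled by the
   maximum magnitude, summarized per network (positive and negative parts
   separately), and flagged important when a feature ranks in the top
   decile on **both** the relative weight and the univariate statistic.

## The tapered window

The default window is 22 TR long (50.6 s at TR = 2.3 s), advanced in steps
of 1 TR, so a 174-point scan yields 153 windows.  The taper is built by
convolving a rectangle of ones (length 22) with a discrete Gaussian of
sigma = 3 TR truncated at ±3 sigma, keeping the central 22 samples, and
renormalizing to sum one.  The construction fixes two details the
rectangular-convolved-with-Gaussian recipe leaves open: the discrete
support of the kernel (±3 sigma captures it to machine precision for
practical sigma) and the normalization (weights as convex combination, so
weighted moments are means).  As sigma → 0 the kernel collapses to a delta
and the window becomes rectangular.

Within each window the correlation is the **weighted** Pearson correlation
under the taper weights — weighted means, weighted covariance, weighted
variances.  Tapering that only multiplied the data would rescale both
series identically and change nothing; the weights must enter the moments
for the taper to mean anything.  A window in which some region has zero
weighted variance yields a zero entry with a warning rather than an error,
since a single flat window should not abort a cohort run.

## L1 k-means and the elbow

All subjects' vectorized windows (strict upper triangle, row-major,
R(R−1)/2 entries) are pooled and clustered jointly, so state labels are
shared across subjects.  Clustering is k-means under the Manhattan
distance: nearest-centroid assignment in L1, centroid updates by
coordinate-wise median (the L1 Fréchet mean), k-means++ initialization,
best of 10 replicates by total L1 inertia, convergence when assignments
stabilize.  An empty cluster is re-seeded at the point farthest from its
current centroid.  Final states are relabeled by descending occupancy, so
"state 1" is always the most visited state — the raw k-means labels are
arbitrary and this makes runs comparable.

The number of states is chosen by the elbow of the cluster-validity ratio

> r(K) = mean L1 distance of windows to their own centroid /
> mean L1 distance of windows to the centroids of the *other* clusters,

computed for K = 2..8, taking the K of maximum discrete curvature
(second difference), ties toward the smaller K.  The denominator follows
the GIFT toolbox convention of measuring between-cluster distance from the
points, not between centroid pairs: with noisy window estimates the
point-based denominator decays once clusters begin to split genuine
states, which produces a clean minimum/kink at the true K, whereas the
mean pairwise centroid distance shrinks mechanically with K and flattens
the curve.  The curve is returned for inspection, and the selection can be
overridden by clustering at any K directly.

On a single Gaussian cloud the ratio decays smoothly and the rule still
returns some K — elbow selection is only meaningful when cluster structure
exists; the returned curve should always be examined.

## State metrics

For a subject's window-level state sequence:

* **mean dwell time** per state is the mean length (in windows) of maximal
  runs of that state, 0 for unvisited states (seconds = windows × step ×
  TR);
* **transition probabilities** are the empirical next-state distributions,
  self-transitions included, with the final window excluded from
  denominators (the standard Markov estimate).  A state with no outgoing
  observations — unvisited, or visited only in the final window — gets the
  identity row (stay with probability one), which keeps the downstream
  feature block finite and is consistent with the constant-sequence case;
* the **transition count** is the number of consecutive-window changes.

Subject centroids are the means of the subject's windows per state;
regional dFC is their node strength after removing negatives.  A subject
who never visits a state has no centroid there; at feature-table assembly
the missing regional-dFC rows are imputed with the cohort mean for that
state and the subjects flagged.  Mean imputation is neutral under the
per-fold z-scoring used by the classifier.

## Classification protocol

The feature table concatenates a covariate block (sex, age, race for the
control-vs-patient task; additionally disease duration, phenotype and
spinal-lesion category for the disability task; categoricals one-hot
encoded with the first level dropped to avoid rank deficiency) with one
connectome block: pairwise SC/FC (3,655 columns at 86 regions), pairwise
dFC (14,620 = 3,655 × 4 states), regional SC/FC (86), regional dFC (344 =
86 × 4), or the 21 dFC metrics (4 dwell times + the full 4×4 transition
matrix + 1 transition count — the only natural decomposition giving 21).

The nested protocol per outer repetition: stratified 5-fold outer split;
within each outer-training set, 5 stratified 5-fold inner partitions; per
candidate penalty, standardize on the inner-training folds, SMOTE the
minority class to balance, fit, and score AUC on the inner-validation
fold; pick the penalty with the best mean inner AUC (ties toward more
regularization); refit on the full outer-training set and evaluate once on
the untouched outer test fold.  With the default 100 outer repetitions
this yields 500 hold-out folds per model.  Standardization precedes SMOTE
because SMOTE's Euclidean neighborhoods are scale-sensitive; covariates
are penalized like all other features (uniform treatment, and ridge
shrinkage handles the scale).  The default penalty grid is 13 points
log-spaced over 10^-3..10^3.

The ridge logistic fit minimizes the mean negative log-likelihood plus
λ‖w‖² with an unpenalized intercept, by damped Newton iteration to
gradient tolerance 1e-8; when p > n the problem is first projected onto
the row space of the design (a thin SVD), which is exact for this
objective and makes the 14,620-column models tractable.  SMOTE generates
minority points by convex interpolation toward one of the k = 5 nearest
minority neighbors until classes balance.

Model comparison uses a paired sign-flip permutation test on the per-fold
AUC differences (models share fold partitions via the same seeds), with
two-sided p = (1 + #{|null| ≥ |obs|}) / (n_perm + 1) and BH correction
across model pairs.

## The synthetic cohort generator

`generate_cohort` emulates exactly the statistical structure the pipeline
assumes, with configurable ground truth:

* **Latent states.** Each subject follows a Markov chain over K = 4 states
  at time-point resolution with self-transition probability 0.992 (mean
  dwell 125 TR, well above the 22-TR window, so window-level states are
  well defined).  The disability group has self-transition 0.999 in state
  1 *and* transitions into state 1 from other states four times as
  readily — the planted dwell-time effect combines longer stays with
  readier entry, which keeps the per-subject dwell distribution away from
  zero and makes the realized group contrast's sign stable at cohort sizes
  of a few dozen (per-subject dwell times are right-censored at the scan
  length and highly variable, so a weaker planted effect would flip sign
  in an appreciable fraction of simulated cohorts).
* **State covariances.** Factor models Σ_k = D + Λ_k Λ_kᵀ (always SPD by
  construction) whose loadings are organized by the 9 networks (Yeo-7 +
  subcortex + cerebellum): each state activates the networks whose index
  has a zero in one bit position, so any two states differ in roughly half
  the networks, and a global ± factor adds state-specific between-network
  positive and negative correlations.  The disability group's loadings in
  the targeted networks (default DAN and VIS, state 2) are scaled by 1.15
  — strong enough to register as a regional-dFC group effect, mild enough
  that the disability group's state-2 windows stay in the same cluster as
  everyone else's (a much larger multiplier would create a genuine fifth
  state).
  Defaults (within-network loading 2.0, cross loading 0.5, residual SD 0.3,
  observation noise SD 0.3) put the cohort in the strong-separation,
  low-noise regime in which state recovery is expected to succeed.
* **SC.** Symmetric nonnegative truncated-normal weights on a sparsity
  mask shared across subjects (density 0.4), so the "nonzero in a strict
  majority of controls" filter is deterministic and testable; MS subjects'
  edges touching DAN/SUB/CER are scaled by 0.8.
* **Demographics** emulate an MS cohort: the disability group is older,
  CIS phenotypes are confined to the no-disability group, EDSS values are
  consistent with the disability split at threshold 2.

What the generator does **not** emulate: hemodynamic autocorrelation,
scanner drift and motion artifacts, spatially correlated noise, lesion
topography, or any relationship between the SC and FC channels.  Passing
recovery tests therefore demonstrates the pipeline's correctness and
calibration on data satisfying its own assumptions — not performance on
real MRI.

## Problem sizes and numerical choices

The packaged analyses and tests run the recovery experiments at 50
subjects (17/17/16), 174 time points and 20 regions with the default
windows — sizes chosen so a full recovery battery (elbow scan over K =
2..8, 10 k-means replicates each, 7,650 pooled windows) completes in tens
of seconds per cohort on one core.  The feature-count checks use the full
86-region atlas.  Calibration experiments (null-cohort cross-validation,
permutation-test uniformity, type-I error) use reduced repetition counts
(20 outer partitions; 200 permutation replicates) that bound their Monte
Carlo error well inside the tolerances being asserted.

Other numerical details fixed by the package: windows are assigned
deterministically given the master seed (all randomness flows through
derived child seeds, `child_seed`); k-means ties and the elbow's curvature
ties resolve toward the smaller K; zero-variance feature columns are
dropped per training fold (their coefficients reported as zero);
correlation values are clipped to [−1, 1] against floating-point overshoot;
the AUC counts ties as one half (Mann-Whitney convention).

## Known limitations

* The elbow rule needs genuine cluster structure; on structureless data it
  still returns an argmax.  Inspect the curve.
* Dwell-time estimates are right-censored by the scan length; with very
  persistent states the group contrast saturates.  The generator defaults
  deliberately stay below that regime.
* The greedy truth-to-cluster matching (`match_states`) assumes reasonably
  separated recovered states; for near-degenerate clusterings an optimal
  assignment could differ.
* The SC prevalence filter is estimated on the controls of the analysis
  cohort itself; in very small control groups it is noisy.
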