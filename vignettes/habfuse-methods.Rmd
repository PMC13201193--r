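---
title: "Methods: habitat subregions and multi-stream fusion for GGN invasiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat subregions and multi-stream fusion for GGN invasiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`habfuse` is a desk-scale, fully synthetic-exercisable implementation of a
multi-scale pipeline for discriminating indolent (AIS/MIA) from invasive
(IAC) lung adenocarcinoma presenting as ground-glass nodules on CT. This
vignette is the package's own account of the modeling choices: what each
stage assumes, which parameters matter, what the synthetic cohort does and
does not emulate, and where the design was genuinely open.

## The phantom cohort

Real cohorts for this problem are private two-hospital collections, so the
package starts from a generator whose **defaults are the study
conditions**, not tuning knobs:

* **Class geometry and attenuation.** Long diameter is drawn from
  N(9.25, 3.63²) mm for AIS/MIA and N(15.66, 5.46²) mm for IAC; patient
  mean attenuation from N(−486.53, 180.75²) HU and N(−338.35, 184.68²) HU
  respectively. Standardized draws are clamped at ±2 so that extreme
  geometry cannot leave the rendered volume while the class means stay
  unbiased; a hard floor of 5 mm (long) / 4 mm (short) keeps every nodule
  analyzable (≥ 27 voxels).
* **Three-zone architecture.** Every nodule is a concentric ellipsoid with
  a dense core (elliptical radius ρ ≤ 0.45), a transition shell
  (0.45 < ρ ≤ 0.8) and a faint rim, with zone attenuations
  (c + δ, c, c − δ) at δ = 80 HU by default. The offset c is chosen so the
  volume-weighted mean equals the patient's drawn attenuation, which makes
  the rendered mean HU and the clinical record agree by construction. The
  three zones give habitat clustering a recoverable k = 3 ground truth:
  at the default noise SD of 15 HU the zone separation is above five
  within-zone SDs.
* **Lobulation.** IAC nodules receive more and larger surface bumps
  (Poisson(4), ≤ 1.8 mm) than AIS/MIA (Poisson(1), ≤ 1 mm). Because
  radiologists measure lobulated nodules edge to edge, the generator
  re-renders each nodule twice, rescaling the in-plane semi-axes so the
  *measured* caliper diameters match the drawn values; the clinical record
  stores the measured quantities.
* **Center effects.** Center 2 adds a +25 HU scanner offset and a 1.2×
  noise multiplier to whole volumes. These are the batch effects the
  harmonization stage is asked to remove.
* **Clinical covariates.** Categorical covariates are class-conditional
  draws with the empirical proportions of the published baseline table
  (e.g. lobulation in 61% of AIS/MIA vs 97% of IAC); age is Gaussian; the
  tumor markers NSE and CEA are lognormal with moment-matched parameters,
  since both are right-skewed in practice.
* **Raters.** A second-rater mask is a random dilation/erosion (radius
  ≤ 1 mm) plus sparse boundary flips — Dice ≥ 0.80 against the original —
  and a repeat perturbation at 0.6 mm stands in for intra-rater
  variability. Perturbations that could empty a mask are refused.

What the phantoms do **not** emulate: lung texture, vessels and bronchi,
partial-volume and reconstruction-kernel effects, DICOM geometry, or any
correlation between covariates beyond their class conditioning. Passing
tests on phantoms therefore demonstrates that the pipeline's statistics,
bookkeeping and protocols are correct — not that its real-data accuracy
matches any published figure. Deep-stream accuracy in particular is not
claimed: see below.

## Preprocessing

Volumes are normalized with the lung window (width 1200 HU, level
−600 HU), mapping −1200 HU → 0 and 0 HU → 1, and resampled to 1 mm³ with a
natural cubic spline applied per axis (nearest neighbor for masks; output
shape `round(shape × spacing)`). Network inputs are ROI-centered: 2D takes
the axial slice with maximal ROI area (10-voxel margin, bilinear resize);
2.5D stacks that slice with its superior and inferior neighbors as three
channels (the neighbor count was unstated upstream; one on each side is
the recorded choice); 3D crops a 64³ cube at the ROI centroid with zero
padding. Windowing precedes the deep streams; radiomics features are
computed on HU values, following common practice for fixed-bin-width
discretization.

## Habitat generation

Each ROI voxel carries 19 local features: raw intensity; 3³-neighborhood
mean, SD, skewness, kurtosis, energy, entropy, range, median, uniformity;
5³-neighborhood mean, SD, entropy; gradient magnitude; Laplacian; LoG
responses at σ = 1, 2, 3 mm; and normalized distance to the ROI boundary.
Neighborhoods clip at volume edges; entropy and uniformity use 32
equal-width bins over the windowed range. Features are z-scored (training
pool statistics) before K-means because K-means is scale-sensitive.
K-means runs with 10 restarts for each k in 2..9, scored by the
Calinski-Harabasz index; ties break toward smaller k for parsimony, and a
zero within-cluster scatter scores `Inf`. Labels are re-indexed by
ascending mean intensity, so h1 is always the darkest subregion.

Two fitting modes exist. Per-nodule fitting (`fit_habitats` on one
nodule's features) recovers the planted k = 3 on three-zone phantoms
essentially always. For cohort-level work, training-nodule voxels are
pooled (seeded per-nodule cap of 5,000 voxels), centroids are fitted once
and frozen, and every nodule in every cohort is labeled with the frozen
centroids (`label_habitats`) — this keeps habitat identities comparable
across patients, at a price discussed under *Limitations*.

## Radiomics and stability

`extract_features` computes, per filter image, 18 first-order, 24 GLCM,
16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features (plus 14 3D shape
features on the original geometry only): 1,595 features under the default
bank of 17 filters (original, LoG σ = 1/2/3 mm, exponential, square,
square root, logarithm, gradient, and the 8 undecimated single-level Haar
sub-bands). GLCM and GLRLM aggregate over the 13 unique 3D directions at
distance 1 (feature values averaged over directions); zones and
dependences use 26-connectivity. Discretization uses a fixed 25 HU bin
width for intensity-scale images (original, LoG, gradient) and a fixed 32
bins for nonlinear filter responses, where a HU-denominated width is
meaningless. Subregions below 27 voxels yield explicit missing values:
texture matrices on a couple of dozen voxels are noise.

Stability filtering computes ICC(2,1) — two-way random effects, absolute
agreement, single measurement — between rater-1 and rater-2 feature tables
(inter-rater) and between rater-1 and its repeat perturbation
(intra-rater); only features with **both** ICCs strictly above 0.75
survive. A zero-variance feature has no defined ICC and is not retained.

## Harmonization and the selection chain

The ComBat-style adjustment estimates per-feature grand parameters and
per-batch empirical-Bayes location/scale posteriors on designated fit rows
only, then applies the frozen transform to every row; a single batch
collapses to the identity with a warning, and zero-variance features pass
through. The package implements the transform itself because the frozen
fit-then-apply contract is central to the no-leakage design; the
established Bioconductor implementation serves as the numerical
cross-check in the test suite (agreement ~1e−7). One property worth
knowing: with few features, EB shrinkage leaves per-feature residual batch
gaps of the order of the batch-mean sampling noise (the reference
implementation leaves the identical residual); batch removal should be
judged in aggregate.

Selection proceeds Pearson → mRMR → LASSO on training rows only:

* **Pearson pruning** (|r| ≥ 0.9): within each correlated pair the member
  with the smaller absolute point-biserial correlation to the label is
  dropped; pairs are processed in descending |r| with a lexicographic name
  tie-break, so the result is deterministic.
* **mRMR** (top 30): greedy MID scheme — relevance is the one-way ANOVA F
  statistic, redundancy the mean absolute correlation with the selected
  set. The implementation is verified against an exhaustive greedy oracle.
* **LASSO**: L1-penalized logistic over glmnet's lambda path, stratified
  seeded 10-fold CV, lambda at minimum mean binomial deviance (the 1-SE
  alternative was considered and not taken: with 30 inputs the extra
  sparsity costs recovery of weak true features in simulation). An
  all-zero solution falls back to the smallest lambda with one nonzero
  coefficient, logged in the trace.

Every stage's frozen parameters live in a `feature_pipeline`, and
`apply_feature_pipeline` is the only path from raw features to model
inputs — corruption of validation/test rows provably cannot change any
fitted statistic.

Where batch harmonization is used in the full study, the batch parameters
are estimated on training + external rows (never validation): the external
center contributes no training labels, harmonization never sees labels at
all, and a frozen transform for center 2 must have seen center-2 rows to
exist. This is the one stage whose fit rows extend beyond the training
cohort, and it is label-blind.

## Deep feature streams

Residual networks of depths 18/50/101 are built natively (im2col
convolutions over BLAS, seeded He initialization, 2D and true 3D
convolution paths) with the standard block structure, so the architecture
contract — a 512-wide (depth 18) or 2048-wide (depths 50/101) global
average pool before the 2-way head — holds exactly. Desk scale dictates
the training regime: the convolutional trunk stays at its seeded random
initialization and acts as a deep structured projection; normalization
layers are identity at unit running statistics; only the linear head is
trained, by full-batch gradient descent on class-weighted cross-entropy
with best-validation-loss checkpointing. Random-projection embeddings
preserve the phantoms' intensity and morphology signal (a linear probe on
them separates the classes), but no claim is made that these embeddings
match trained-network accuracy on real CT — pretrained medical 3D
backbones are unavailable here, and this deviation is deliberate and
documented rather than hidden behind a partially trained network.
Stream choice among the nine depth × mode candidates is by validation
AUC with ties broken toward the shallower depth, then the
lower-dimensional input mode.

## Base models and fusion

All classifier heads are RBF-SVMs with seeded 5-fold grid search
(C ∈ {0.1, 1, 10, 100}; γ ∈ {1/(p·var), 0.01, 0.001}) scored by
cross-validated AUC. Probabilities come from a Platt sigmoid fitted to
out-of-fold decision values of the winning configuration — never to
in-sample decision values. Decision values are re-oriented explicitly
(positive ⇒ class 1) because the underlying solver orients them by
training-row order, a subtle trap when a calibration fitted on fold models
is applied to a full refit.

The clinic stream does not use the radiomics chain: univariate logistic
screening (p < 0.05) feeds a multivariate logistic model, and its p < 0.05
survivors — the independent risk factors — are the clinic model's
features. Separation is detected and refit with a small ridge penalty,
flagged.

Early fusion concatenates the raw stream tables into one joint space and
runs the identical chain (prune → mRMR → LASSO) before the SVM; retained
names keep their stream prefixes. Late fusion is a stacking ensemble: 5
seeded stratified folds, each base stream's *entire* preprocessing and
classifier refit per fold, out-of-fold probabilities assembled into the
n × 4 meta-feature matrix, and an SVM meta-learner trained on it; at
inference the base models are refit on the full training set. The fold
bookkeeping (which rows each fold's fits saw) is stored in the
`StackingPlan` and asserted in tests; a fixed fold assignment can be
supplied, which is also how the label-flip leak check is made
well-defined (fold draws themselves depend on labels through
stratification).

## Evaluation and interpretation

* **ROC/AUC**: midrank Mann-Whitney AUC (equal to exhaustive pair counting
  with half-weight ties), DeLong structural-component variance, Wald 95%
  CI truncated to [0, 1]. Classification thresholds maximize the Youden
  index on the training cohort and are frozen for validation/test —
  per-cohort re-optimization would flatter the external results.
* **Paired DeLong**: covariance of the two models' structural components;
  a zero-variance difference returns p = 1 with a warning. Agreement with
  a 2000-replicate bootstrap of the AUC difference is part of the test
  suite.
* **Hosmer-Lemeshow**: decile-of-risk bins (empty bins merged),
  χ² = Σ (O−E)²/(E(1−E/n)), df = bins − 2. The df = bins − 2 reference is
  the classical result for in-sample fitted probabilities; for externally
  specified probabilities the statistic is stochastically larger, so
  calibration of, e.g., hand-constructed scores should be read with that
  in mind.
* **Decision curves**: NB(pt) = TP/n − FP/n · pt/(1−pt) against treat-all
  and treat-none; pt = 1 is excluded.
* **Cohort statistics**: Shapiro-Wilk gates pooled-variance t (both groups
  normal) versus Wilcoxon rank-sum; 2×2 tables use the Yates-corrected χ²
  (the correction truncates at zero, so a table with ad = bc gives p = 1),
  expected cells below 5 switch to Fisher's exact test, r×2 tables use the
  plain Pearson χ². The engine reproduces the printed p-values of the
  motivating cohort's baseline table exactly after rounding to 3 decimals,
  including the pooled-vs-Welch distinction on the external-cohort age
  row.
* **Shapley attributions**: permutation-sampling estimator on the
  post-selection feature space with ~20 medoid background rows; every
  permutation chain telescopes from a background row to the explained row,
  so additivity (base + Σ attributions = prediction) holds exactly, not
  approximately. Exact coalition enumeration (≤ 12 features) is provided
  as the reference and used in tests (agreement within 0.01 at 500
  permutations).

## Numerical choices and degenerate inputs

Ties in CH break toward smaller k; ties in mRMR and pruning break on
feature names; empty LASSO solutions fall back with a logged flag;
zero-variance features are dropped at z-scoring (population-SD convention)
and passed through harmonization; subregions under 27 voxels are missing,
then features missing in more than 10% of training rows are dropped and
the rest median-imputed from training. For the habitat stream that 10%
rule needs care: with pooled centroids and realistic between-patient
attenuation spread (SD ≈ 180 HU against an 80 HU zone contrast), many
patients occupy only one or two of the three frozen clusters, so
per-patient subregions frequently fall under 27 voxels and *every* habitat
feature can exceed a 10% missing rate. The module default stays at 0.1;
the study driver passes 0.5 for subregion-bearing tables and lets median
imputation fill the gaps. This is a property of cohort-level habitat
analysis itself, not of the phantom: per-patient habitat occupancy is
genuinely uneven.

## Problem sizes

The shipped tests and the acceptance script run, by the package's own
choice, at desk scale: cohorts of 34–40 center-1 and 20 center-2 patients,
48³-voxel volumes, a reduced radiomics bank (the full 1,595-feature bank
is exercised on single nodules), depth-18 2D networks at 16–32 px for the
end-to-end study with the depth-50 contract checked by direct forward
passes, 100-seed habitat-recovery sweeps, and 200-replicate calibration
simulations. Every quantity is recomputed from a single seed; the full
study is byte-reproducible.

## Known limitations

* Voxel-level agreement between fitted habitats and the planted zones
  saturates near 0.7: the phantom rim is only 1–2 voxels thick, so the
  neighborhood features that drive the clustering are blends across zone
  boundaries there. Recovery of the *number* of habitats is robust (k = 3
  in ≥ 95% of seeded runs); recovery of exact voxel assignments at thin
  interfaces is not, and the package does not claim it.
* Pooled (cohort-level) centroids on heterogeneous cohorts can prefer
  k ≠ 3, because between-patient attenuation differences compete with
  within-nodule zones; whether habitat clustering should be pooled or
  per-patient is an open methodological question, and the package
  implements pooled fitting as its recorded choice while exposing
  per-nodule fitting too.
* Deep embeddings come from seeded random-initialization trunks; they are
  a structured projection, not a trained representation.
* The phantom's clinical covariates are marginally faithful but
  conditionally independent given the class; real covariates correlate.
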