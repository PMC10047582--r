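---
title: "Voxelwise recurrence mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise recurrence mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(recurmap)
```

## The prediction problem

After complete resection of the enhancing tumor, glioblastoma recurs from
the peritumoral region — the FLAIR/T2-hyperintense zone around the cavity
that mixes vasogenic edema with infiltrating tumor. The package predicts,
voxel by voxel, which parts of that region will become enhancing tumor on
follow-up, using only the postoperative multiparametric MRI (T1w, T1ce,
T2w, FLAIR, ADC) together with a cavity mask and a peritumoral mask.
Ground truth is the deterministic set operation on the follow-up scan:
peritumoral voxels overlapping the follow-up enhancing-tumor segmentation
are labeled recurrence (1), the remainder nonrecurrence (0). Registration,
bias correction, brain extraction and the segmentations themselves are
inputs, not part of the package.

## Pipeline and assumptions

**Normalization.** Intensities are z-scored within a support mask
(`zscore_normalize`). The support is assumed to be the whole brain; this
is configurable because the convention cannot be recovered from typical
study descriptions. The population (1/n) standard deviation is used —
self-consistent and the common imaging convention; the sample convention
is available via `sd_type`.

**Filter bank.** Three filters complement the original volume:

* *Laplacian of Gaussian* (`log_filter`): Gaussian smoothing at a world-space
  scale σ (mm, converted to voxels through the spacing) followed by the
  discrete Laplacian in world units, multiplied by σ² (scale
  normalization). Defaults σ ∈ {1, 2, 3} mm span fine to coarse blob
  scales at 1 mm resolution. With discrete kernels the extremal response
  for a Gaussian blob of scale *s* lands near σ ≈ *s* (the continuous
  optimum of the σ²-normalized operator is at σ = s/√1.5, so the argmax
  over an integer grid sits at *s* or one step below).
* *Wavelet* (`wavelet_decompose`): one-level separable orthonormal Haar
  analysis giving 8 sub-bands; odd axes are replicate-padded (which breaks
  exact energy conservation on those axes — the Parseval property is exact
  for even lengths). For voxelwise use each decimated band is expanded
  back to source resolution by nearest-neighbour repetition.
* *Local binary patterns* (`lbp3d`): each voxel's six face neighbours are
  thresholded against the centre (ties count as ≥, replicate padding at
  edges) and the pattern is reduced to its set-bit count, a
  rotation-invariant code in 0..6. A constant image therefore maps to 6
  everywhere, and an isolated maximum to 0.

**Features.** Feature definitions follow the IBSI descriptions: 19
first-order statistics and 75 texture features (GLCM 24, GLRLM 16,
GLSZM 16, NGTDM 5, GLDM 14). Conventions that the IBSI leaves open, fixed
once here:

* grey levels: 16 equal-width bins over the local kernel range (robust for
  small kernels after z-scoring); constant kernels map to level 1;
* GLCM/GLRLM: 13 unique distance-1 directions, features computed per
  direction and averaged (the deterministic "averaged" aggregation);
* GLSZM zones and NGTDM/GLDM neighbourhoods use 26-connectivity at
  distance 1;
* GLDM dependence of a voxel is 1 (the centre) plus the number of valid
  neighbours within level tolerance α = 0, so dependence is ≥ 1;
* percentiles interpolate linearly between order statistics;
* first-order statistics are computed on the raw (z-scored, undiscretized)
  kernel values except entropy and uniformity, which use the discretized
  histogram; skewness and kurtosis are population-convention and defined
  as 0 at zero variance; kurtosis is not excess-corrected;
* degenerate texture matrices take their analytic limits (single-entry
  GLCM: joint energy 1, entropy 0, correlation 1, MCC 1), never NaN; log
  terms are guarded by machine epsilon.

Feature maps are computed on the cubic kernel of radius 2 (5×5×5; the
extraction kernel is not recoverable from typical study texts, and this is
the common voxel-based radiomics choice) centered at each peritumoral
voxel, intersected with the brain support; kernels with fewer than 8
support voxels are computed on what is available and flagged in a QC
vector. The result is invariant to voxel visiting order. The manifest
(`feature_manifest`) names every column `modality_filter_family_feature`
and makes any configuration's feature count explicit — the full bank is
5 modalities × 13 filtered images × 94 features = 6110 columns; no total
is hard-coded anywhere.

**Balancing and classifiers.** Recurrence voxels are the small minority,
so the pooled training rows are balanced by randomly undersampling the
majority class to the minority size (`undersample`; pooled across cases
rather than per case, because the study design reports a single pooled
count — the per-case variant can be had by calling it per table). Four
ensemble classifiers sit behind `recur_fit`:

* `catboost` — oblivious-tree (symmetric-tree) gradient boosting with
  logistic loss, implemented in the package in C++: histogram splits
  (64 quantile bins), one shared split per tree level, depth 6, 100
  rounds, learning rate 0.1, L2 λ = 1. Fully deterministic; split ties
  resolve to the lowest feature index.
* `xgboost` — depth-wise histogram boosting (max depth 6, η = 0.1, 100
  rounds) via the xgboost backend.
* `lightgbm` — leaf-wise (loss-guided) growth, the defining growth policy
  of light gradient boosting, with 31 leaves, run through the xgboost
  backend.
* `random_forest` — 200-tree probability forest (ranger backend).

Hyperparameters are fixed defaults with a documented iteration cap, not
tuned — reproducibility is preferred over tuning, and no reference
settings exist to match. Predicted probabilities are used as scores
downstream (rank calibration only), and the positive class is recurrence.

**Probability maps and labels.** Infiltration concentrates near the
cavity, so predicted probabilities are attenuated beyond a cutoff
distance: multiplier 1 up to 15 mm from the cavity edge and
exp(−0.5·(d−15)) beyond — continuous at the cutoff, nonincreasing, never
increases any probability. Only the attenuation's existence and its 15 mm
anchor follow the study design; the exponential form and the 0.5/mm rate
are this package's choice of a continuous one-parameter family, both
exposed in `correction_config`. Distances are exact Euclidean distance
transforms in world millimetres (anisotropic spacing honoured). The
corrected map is binarized at the Otsu threshold of its within-peritumor
scores — per case, not pooled, so one case's predictions never depend on
another's scores; the threshold maximizes between-class variance over a
256-bin histogram, with ties resolved to the mean of the maximizing cuts.
Applying the correction twice is a guarded error (stage flag).

**Evaluation.** Voxelwise: AUC from the continuous corrected scores
(midrank/Wilcoxon formula, invariant under strictly increasing
transforms), accuracy/precision/recall/F1/kappa from the thresholded
labels; kappa is (p₀ − pₑ)/(1 − pₑ); undefined precision (no positive
predictions) is reported as 0 with a flag; single-class truth yields a
reasoned missing AUC. Region-based: the peritumor is partitioned into 26
directional sectors around the cavity centroid — per axis the unit
displacement is negative/neutral/positive with a ±22.5° neutral band, and
the sign triple names faces (anterior, posterior, superior, inferior,
right, left), edges and corners; the all-neutral triple is geometrically
impossible for a nonzero displacement, and a voxel exactly at the
centroid falls back to its largest-displacement axis. A sector is positive
when positive voxels reach 1% of its size (applied identically to truth
and prediction — the activation rule is a package choice, robust to
single-voxel noise); the sector score for AUC is the 95th percentile of
within-sector corrected probabilities (max is noise-fragile, mean dilutes
focal signal; both remain available). Cohort aggregation reports
mean ± SD per metric and mode, population-SD convention, excluding (and
counting) cases with missing values.

## The synthetic phantom

`generate_phantom` builds, per case: a spherical cavity (radius 8 mm), a
peritumoral shell (12 mm wide), a brain support sphere 4 mm beyond the
shell, and a cone-shaped recurrence subregion of 60° apex angle reaching
10 mm beyond the cavity edge — concentrated near the cavity as real
infiltration is. The follow-up mask is the recurrence region plus a bulge
into the cavity, so the label derivation's clipping is exercised. Five
modality channels share a latent Gaussian random field (weight 0.5) mixed
with per-modality fields and white noise (SD 0.5 relative to the
unit-variance texture), emulating multiparametric redundancy. Random
fields are generated on a padded grid, smoothed separably (correlation
length 3 mm), cropped, and normalized analytically, so the marginal
variance is exactly one and stationary.

`effect_size` is the standardized shift of the recurrence-class mean in
units of the total per-voxel SD, scaled per modality by `modality_effect`
(largest on T1ce, negative on ADC — diffusion drops in cellular tumor).
The default condition is d = 2, a deliberately strong positive control:
at that separation the full pipeline should — and does, in the acceptance
tests — recover the seeded region almost perfectly, while d = 0 must sit
at chance. Three generator choices exist specifically to make d = 0 an
*exact* null, so that any held-out signal at zero effect indicts the
pipeline rather than the phantom:

* the two class texture fields share one continuous realization unless
  explicitly re-textured — independent per-class fields would leave a
  detectable texture discontinuity at the region boundary;
* equal default correlation lengths per class — class-distinct smoothness
  is itself a (legitimate, optional) contrast channel via
  `texture_corr_len_mm`;
* no default cavity intensity shift — a darkened cavity would let kernels
  encode distance-to-cavity, which correlates with the label by
  construction; `cavity_intensity_shift` re-enables it for realism.

The phantom deliberately does **not** emulate anatomy, registration
error, mass effect, or pseudoprogression. Passing tests on phantoms
therefore demonstrate that the machinery is correct and recovers known
signal under controlled conditions — not that the pipeline's clinical
accuracy on patient data is reproduced.

Cohorts (`generate_cohort`) jitter the cavity center (±4 mm) and draw a
random recurrence direction per case from per-case subseeds, with
train/test case ids disjoint; the 40/15 design mirrors the reference
study's cohort split.

## Problem sizes and determinism

The validation runs use 40 training and 15 testing cases on 64³ grids at
1 mm — about 31,000 peritumoral voxels per case, ~120,000 balanced
training rows of 95 features (first-order on the original images; the
texture families and the full filter bank are exercised on smaller grids,
where their brute-force oracles are feasible). Property-style tests use
36³ phantoms. Every stage's randomness derives from one root seed
(`run_config$seed` expanded per stage); the categorical-boosting path is
bit-deterministic, so identical configs reproduce identical metrics.

## Known limitations

* The exact extraction settings of the reference workflow (kernel, bins,
  filter-bank composition behind its printed 4730-feature total) are not
  recoverable; the manifest is configurable instead and the package makes
  each configuration's count explicit.
* The `catboost` and `lightgbm` ids implement those algorithms' defining
  tree-growth strategies (oblivious trees; leaf-wise growth) rather than
  binding the upstream libraries; ordered boosting and categorical-feature
  handling are out of scope (all features here are numeric).
* Voxelwise texture-family extraction is O(kernel × matrix) per voxel and
  is meant for regions/small grids at desk scale; the first-order path is
  the optimized default for cohort-scale runs.
* Sector evaluation depends on the activation fraction; at weak effect
  sizes scattered false-positive clusters activate extra sectors and
  sector accuracy degrades long before sector AUC does.
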