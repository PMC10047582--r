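# recurmap

Voxelwise radiomics mapping of glioblastoma recurrence in the peritumoral
region.

## The problem

Glioblastoma surgery removes the contrast-enhancing tumor, but the
FLAIR-hyperintense peritumoral region left behind mixes vasogenic edema
with infiltrating tumor cells, and local recurrence almost always grows out
of that zone. If the infiltrated parts of the peritumor could be identified
on the immediate postoperative MRI, supramarginal resection or radiotherapy
boosts could target them months before they enhance.

`recurmap` implements a voxelwise prediction pipeline for this task, aimed
at imaging scientists working with coregistered, brain-extracted, 1 mm
isotropic postoperative multiparametric MRI (T1w, T1ce, T2w, FLAIR, ADC)
plus surgical-cavity, peritumoral and follow-up enhancing-tumor masks. A
synthetic multiparametric phantom generator with known ground truth makes
every stage runnable and testable without patient data.

## The method

For each peritumoral voxel \(v\):

1. **Ground truth.** \(y(v) = 1\) if \(v\) lies in the overlap of the
   peritumoral mask with the follow-up enhancing-tumor mask (recurrence),
   else \(y(v) = 0\) (edema).
2. **Features.** Each modality is z-scored within the brain
   (\(x \mapsto (x-\mu)/\sigma\), population \(\sigma\)), passed through a
   filter bank (original, Laplacian-of-Gaussian at \(\sigma \in \{1,2,3\}\)
   mm, one-level 3D Haar wavelet, 3D local binary patterns), and IBSI-style
   features are computed on the cubic kernel of radius 2 centered at
   \(v\): 19 first-order statistics and 75 texture features (GLCM 24,
   GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14) on 16 equal-width grey levels.
3. **Balancing and training.** The pooled training voxels are balanced by
   randomly undersampling the majority (nonrecurrence) class to the
   minority size; four classifiers are available behind one interface —
   `catboost` (oblivious-tree gradient boosting, implemented in the
   package), `xgboost` (depth-wise histogram boosting), `lightgbm`
   (leaf-wise/loss-guided histogram boosting) and `random_forest`.
4. **Probability maps.** Predicted probabilities \(p(v)\) are attenuated
   by a cavity-distance correction factor
   \(f(d) = 1\) for \(d \le 15\) mm, \(f(d) = e^{-0.5 (d - 15)}\) beyond,
   with \(d\) the Euclidean distance (mm) from the cavity edge; the
   per-case Otsu threshold of the corrected map defines the predicted
   recurrence label.
5. **Evaluation.** Voxelwise and region-based: the peritumor is divided
   into 26 directional sectors around the cavity centroid (6 faces, 12
   edges, 8 corners); a sector is positive when ≥ 1% of its voxels are.
   Both modes report AUC, accuracy, precision, recall, F1 and Cohen's
   kappa as mean ± SD over cases.

## Worked example

```r
library(recurmap)

spec <- phantom_spec(grid_shape = c(48, 48, 48), cavity_radius_mm = 6,
                     shell_thickness_mm = 9, recurrence_depth_mm = 8,
                     effect_size = 2)
cfg <- run_config(phantom = spec, n_train = 4, n_test = 2,
                  algorithms = "catboost", seed = 11)
res <- run_all(cfg)

print(res$models$catboost)
#> <recur_model> catboost (oblivious backend), 5668 training voxels (2834/2834 per class), 95 features

subset(res$summary, metric %in% c("auc", "accuracy", "kappa"),
       select = c(mode, metric, formatted))
#>      mode   metric   formatted
#> 1  sector      auc 1.00 ± 0.00
#> 2  sector accuracy 0.92 ± 0.04
#> 6  sector    kappa 0.78 ± 0.12
#> 7   voxel      auc 1.00 ± 0.00
#> 8   voxel accuracy 0.97 ± 0.00
#> 12 voxel     kappa 0.78 ± 0.02

head(feature_importance(res$models$catboost)$ranking, 3)
#>                           feature importance cumulative
#> 1     ADC_original_firstorder_p10  0.4605688  0.4605688
#> 2    T1ce_original_firstorder_p90  0.1328270  0.5933959
#> 3 ADC_original_firstorder_minimum  0.1241625  0.7175584
```

The six simulated cases share the cavity/shell geometry with jittered
centers and random recurrence directions; training balanced 2834
recurrence against 2834 undersampled nonrecurrence voxels. Held-out voxel
AUC of 1.00 and sector accuracy of 0.92 say the classifier separates the
shifted recurrence signal nearly perfectly at this large effect size
(standardized shift d = 2); kappa near 0.78 reflects the residual
overprediction that per-case Otsu thresholding leaves. ADC and T1ce
first-order statistics dominate the importance ranking, as expected when
the phantom's strongest modality shifts are on ADC (negative) and T1ce
(positive).

Individual stages are also available directly: `generate_phantom()` /
`generate_cohort()`, `read_volume()` / `zscore_normalize()` /
`resample_isotropic()`, `derive_labels()`, `build_feature_table()`,
`undersample()` / `recur_fit()` / `predict()`, `distance_from_cavity()` /
`distance_correction()` / `otsu_threshold()` / `predicted_labels()`,
`sector_partition()` / `voxel_metrics()` / `sector_metrics()` /
`aggregate_cohort()`. A thin command-line wrapper lives at
`inst/cli/recurmap` (subcommands `simulate`, `extract`, `train`,
`predict`, `evaluate`, `run-all`).

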