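# picafuse

Joint spatial decomposition of paired brain-imaging modalities by
**parallel independent component analysis (pICA)**, written for studies that
ask how two molecular imaging maps — canonically tau-PET (AV1451) and
amyloid-PET (AV45) in mild cognitive impairment — covary across subjects.

Each modality's subjects × voxels matrix `X_m` is modelled as

```
X_m = A_m S_m + E_m ,   m = 1, 2
```

where the rows of `S_m` are independent spatial component maps, the columns
of `A_m` are per-subject **loading parameters** (the contribution of each
component to the between-subject variance), and `E_m` is noise. Each
modality is whitened to `k` principal axes and unmixed by natural-gradient
infomax ICA; in parallel, the correlation between the most strongly coupled
pair of cross-modal loading columns is adaptively enhanced, so that a shared
subject-level process expressed in both modalities is estimated as a single
linked pair of networks. Around the decomposition the package provides:

- a paired-modality **synthetic-data generator** with known spatial sources,
  a coupled loading pair and group-discriminative components, for validation;
- **model-order selection** from the eigenvalue spectrum (Wax–Kailath AIC,
  with MDL reported alongside);
- **component statistics**: Welch tests of loadings between groups,
  voxel-wise maps, all-pairs cross-modal Pearson correlations with
  Benjamini–Hochberg FDR, covariate screens, cohort demographics tables;
- **atlas-style reporting**: z-scored maps thresholded at |z| > 2.5,
  connected-component peaks, region/network labels, MNI-style mm
  coordinates;
- **classification**: ROI features from significant components, stratified
  5-fold cross-validation with ACC/AUC/SEN/SPE on the percent scale, under
  Non / Tau / Abeta / All feature conditions.

## Worked example

```r
library(picafuse)

cfg <- sim_config(seed = 2)            # 65 MCI / 75 NC, 8 sources/modality,
ds  <- synthesize_dataset(cfg)         # coupled pair at r = 0.6, noise 0.1
fit <- parallel_ica(ds$tau, ds$abeta, pica_config(seed = 2))
glance(fit)
#> # A tibble: 1 × 8
#>   n_components_1 n_components_2 epochs converged max_crossmodal_r best_pair_i best_pair_j n_constrained
#>            <int>          <int>  <int> <lgl>                <dbl>       <int>       <int>         <int>
#> 1              8              8    689 TRUE                 0.730           2           1             1

# how well were the planted sources recovered?
match_components(fit, ds$truth$sources[[1]], modality = 1)
#> <component_match> mean matched |r| = 0.9909, Amari index = 0.0322

# which components separate the groups, and which cross-modal pairs survive FDR?
tests <- loading_group_test(fit$modalities$tau$loadings,
                            ds$truth$group_labels, modality = "tau")
dplyr::filter(tidy(fit), abs(r) > 0.5)
#> # A tibble: 1 × 4
#>       i     j     r constrained
#>   <int> <int> <dbl> <lgl>
#> 1     2     1 0.730 TRUE
```

The fitted maximum cross-modal loading correlation (0.730 here) is the
synthetic analogue of the coupled tau–amyloid default-mode pair such studies
report; its exact value varies with the seed inside the sampling band of the
planted r = 0.6. The whole pipeline — simulation or NIfTI loading,
preprocessing, order selection, decomposition, statistics, peak tables,
cross-validated classification — runs from one config:

```r
res <- run_pipeline(run_config(simulate = cfg, seed = 2))
res$classification$summary
res$manifest$stages
```

## Package shape

Data matrices travel in a light `voxel_matrix` container (values + mask +
affine + subject ids); everything statistical returns a tibble, fitted
objects have `tidy()`/`glance()` methods, and every result type has an
`autoplot()` (correlation heatmap, criterion curves, ROC). See the methods
vignette (`vignettes/picafuse-methods.Rmd`) for the model, the optimiser,
parameter defaults and their rationale, and known limitations.
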