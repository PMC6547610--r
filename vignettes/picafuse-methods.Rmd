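---
title: "Methods: constrained parallel ICA for paired PET modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained parallel ICA for paired PET modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

picafuse decomposes two paired subjects × voxels matrices, one per imaging
modality, as `X_m = A_m S_m + E_m`. The orientation is *spatial* ICA: the
rows of `S_m` are statistically independent spatial maps over the in-mask
voxels, and the columns of `A_m` are per-subject loading parameters. This
matches how molecular-PET covariance studies present their results — spatial
component maps rendered on the brain, with subject loadings carried into
group tests — and it makes the cross-modal question precise: two components
(one per modality) are *linked* when their loading columns are correlated
across subjects, i.e. when the same subjects express both patterns strongly.

Each modality is first reduced by PCA. Rows are centred (each subject's mean
over in-mask voxels removed), the between-subject covariance is
eigendecomposed, and the top `k` axes are whitened. The number of components
defaults to 8, the standard choice for this family of analyses; it can also
be estimated per modality from the eigenvalue spectrum with the Wax–Kailath
criteria (below).

Unmixing uses full-batch natural-gradient infomax with a logistic
nonlinearity:

```
W <- W + eta * (I + (1 - 2 g(WX)) (WX)' / N) W
```

This update's fixed points separate super-Gaussian sources, which is why the
synthetic generator builds its spatial sources as sparse positive blobs
(right-skewed, super-Gaussian over voxels) — the same regime as real
component maps, which are near-zero over most of the brain and strongly
positive in a network.

### The cross-modal constraint

After a burn-in of unconstrained epochs, the engine computes all
cross-modal loading correlations each epoch. For up to `max_constrained_pairs`
pairs (default 1) whose |r| exceeds the activation threshold (default 0.3),
it takes a gradient-ascent step on r² with respect to the two loading
columns and propagates it to the unmixing weights through the dewhitening
relation `A = D W^{-1}`: the step is applied to the corresponding column of
the whitened-space mixing matrix `M = W^{-1}` (since `A = D M` is linear,
`∂/∂M = D' ∂/∂A`), after which `W` is re-inverted.

Two stability rules matter in practice:

- **Anti-overshoot.** The strength λ (default 0.05) is halved whenever the
  constrained |r| grows by more than 0.05 within one epoch. Without this the
  constraint can manufacture correlation that is not in the data.
- **Conditioning guard.** A constraint step that would push the mixing
  matrix `M` towards singularity (condition number above 1e6) is skipped and
  λ halved instead. `W = M^{-1}` would otherwise explode and the infomax
  iteration diverges irrecoverably; this failure mode occurs on a small
  fraction of random initialisations and is fully prevented by the guard.

If an infomax step still diverges (any |W| beyond 1e9), that modality is
restarted from its initial weights at a learning rate annealed by 0.9 —
restarting, rather than reverting one step, is what actually recovers a
blown-up iteration.

One caveat surfaced by testing: at small subject counts, a *chance*
cross-modal correlation can cross the 0.3 activation threshold (the null SD
of r is about `1/sqrt(n)`, so at n = 60 chance values above 0.3 are common).
The threshold should be raised for small panels; at the default n = 140 the
planted coupling dominates.

### Scale and sign conventions

ICA leaves per-component scale and sign undetermined. On return every source
row has zero mean and unit variance over the mask, loadings carry the
magnitude, and signs are chosen so each source map's skewness is
nonnegative (flipping the loading column jointly, so `A S` is unchanged).
Reported maps are additionally z-scored and thresholded at |z| > 2.5
(strict) for peak tables.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_components` | 8 | components per modality; the conventional fixed choice, with AIC estimation as an override |
| `learning_rate` | 0.02 | natural-gradient step. Chosen so the default-size problem (8 comps, ~5000 voxels) converges in under ~1000 epochs; much smaller rates under-converge within any reasonable epoch cap, larger ones oscillate |
| `tolerance` | 1e-6 | epoch-to-epoch max |ΔW| at convergence |
| `max_iterations` | 2000 | epoch cap; non-convergence is a warning, not an error |
| `constraint_threshold` | 0.3 | activation |r|; see the small-n caveat above |
| `lambda` | 0.05 | initial constraint strength, adaptively halved |
| `burn_in` | 20 | unconstrained epochs before the constraint may engage |
| z cutoff | 2.5 | report threshold on component z-maps |
| FDR α | 0.05 | Benjamini–Hochberg level for the 8×8 correlation table |
| k (folds) | 5 | stratified cross-validation folds |
| FWHM | 8 mm | Gaussian smoothing for real volumes; simulated data is generated in template space and skips smoothing by default |

## Model-order selection

`estimate_order()` evaluates, for each candidate order `k`, the Wax–Kailath
log-likelihood term `N (p−k) log(a_k/g_k)` built from the arithmetic and
geometric means of the trailing eigenvalues, penalised as AIC
(`+ 2k(2p−k)`) or MDL (`+ ½ k(2p−k) log N`). Selection uses the AIC
minimiser; the MDL curve is reported alongside as the conservative
criterion (it chooses an order ≤ AIC's in the large majority of noisy
simulations) but is never used to select. Two numerical choices: eigenvalues
are floored at 1e-12 × the largest before the log, so exactly low-rank
(noise-free synthetic) input stays finite; and the effective sample size is
taken as the voxel count, although spatial smoothness makes voxels
non-independent — no subsampling correction is applied, and the returned
object carries that caveat. At `k = p−1` a single trailing eigenvalue makes
the ratio term exactly zero, so the criterion reduces to the penalty.

## What the generator emulates — and what it does not

The defaults encode the study conditions the package is validated under:
140 subjects in groups of 65 (MCI) and 75 (NC); two modalities on a shared
20×24×20 grid at 4 mm inside an inscribed-ellipsoid mask (~5000 voxels);
8 spatial sources per modality, each a sum of 2–4 Gaussian blobs (FWHM
12 mm) with pairwise map |correlation| ≤ 0.3; Gaussian loadings with one
cross-modal pair coupled at r = 0.6 via a bivariate-Gaussian draw; a group
mean shift of d = 0.8 SD on a subset of components (m1: 2,3; m2: 4,5 —
disjoint across modalities so that fusing features is genuinely
informative); additive voxel noise with SD 0.1. The coupling target 0.6
mirrors the magnitude of the strongest tau–amyloid loading correlation such
studies report; no published effect sizes exist for the group-different
components, so d = 0.8 (a conventional "large" effect) was fixed once.
Realised values (coupling, per-component Cohen's d) are recorded in the
truth object, because at n = 140 the realised coupling varies in roughly
0.6 ± 0.15.

Deliberately not simulated: scanner physics, partial-volume effects, frame
averaging, SUVR kinetics, spatial normalisation error, and spatially
correlated noise. Passing recovery tests on this generator therefore shows
the estimator is correct under its own model assumptions — independent
sparse sources, linear mixing, i.i.d. noise — not that real PET data
satisfies those assumptions; the limitations of applying ICA to PET (voxel
independence, uniform noise) remain.

## Statistics

Component-level significance is a Welch two-sample t-test on each loading
column (the primary criterion, matching the way component p-values are
reported per component); the voxel-wise Welch map is a secondary output.
Welch rather than pooled-variance everywhere, because group sizes and
variances differ. Cross-modal inference computes all `k1 × k2` Pearson
correlations with p from the t transform (df = n−2) and BH adjustment
across the pairs (BH, not BY: the field default). The cohort table uses
Welch t for continuous measures, 2×2 chi-square without continuity
correction (cell counts are large), and a Mann–Whitney normal approximation
with tie correction for CDR. FDR is applied only to the correlation table,
not to voxel-level maps.

## Classification

ROI features are per-subject mean intensities over each significant
component's thresholded |z| mask; `All` concatenates both modalities. The
`Non` baseline (undefined in the source experiment beyond being a raw-data
comparison) is each modality's whole-mask mean plus the top-5 PCA scores of
the concatenated raw data. On the low-rank synthetic data this baseline is
*not* weak — the top principal components capture the group-shifted latent
dimensions — so `Non` accuracies here sit well above the near-chance values
seen on real, high-rank data. The qualitative target the suite checks is
the fusion ordering: `All` above each single modality.

The classifier is L2-penalised logistic regression (glmnet, ridge,
λ = 1/n; decision values as scores), the simplest defensible choice for
~20 features at n = 140, with features standardised inside each training
fold only. Metrics are ACC, rank-based AUC (half credit for ties),
sensitivity on MCI, specificity on NC, all ×100, averaged over the 5 fold
values; folds are stratified so a 65/75 panel splits 13+15 per fold.
Per-fold averaging (rather than pooling scores) is the default reading of
"averaged over the five runs"; pooled ROC coordinates remain available for
plotting. The strict protocol — re-running the decomposition and the
significance screen inside every training split — is available as
`classify = list(refit_per_fold = TRUE)` and flagged in the report; the
default fits components once on the full panel, which is faster and is the
variant most published pipelines actually report.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on reduced conditions (12×14×12 grids, 3–4 components,
~60 subjects) chosen so each property is still informative; the acceptance
checks and `scripts/acceptance.R` use the full default conditions above —
one full constrained fit for source recovery, 3 seeds for coupled-pair
recovery, 10 constrained/unconstrained seed pairs for the constraint-benefit
rate, 500 replicates for FDR calibration, 2000 null components for test
calibration, 20 replicates for order selection, and 10 full
pipeline-plus-CV replicates for the fusion ordering.

## Known limitations

- Two modalities only; no three-way extension, no ICASSO-style stability
  resampling.
- The constraint enhances the single strongest pair by default; multiple
  simultaneously coupled pairs are supported (`max_constrained_pairs`) but
  the adaptive-λ history is shared, and the estimated |r| of a constrained
  pair is biased upward by roughly 0.03–0.07 relative to the unconstrained
  estimate under the default λ.
- Voxel-wise maps receive no multiple-comparison correction (by design —
  FDR applies to the correlation table only).
- The order-selection criteria treat voxels as independent samples;
  smoothness-corrected variants are out of scope.
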