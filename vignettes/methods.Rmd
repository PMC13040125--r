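---
title: "Ultrasound radiomics for uterine sarcoma risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound radiomics for uterine sarcoma risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Preoperative discrimination between uterine sarcomas and benign
leiomyomas from grayscale ultrasound is clinically consequential and
subjectively difficult. The radiomics approach implemented here treats a
single B-mode image per tumor, with a manually drawn region of interest
(ROI) covering the solid lesion component (cystic areas larger than 5 mm
in diameter excluded), as a source of quantitative descriptors, and builds
risk models on those descriptors with or without patient age.

The pipeline stages, in order:

1. **Speckle reduction.** A locally adaptive Wiener filter with a 3 × 3
   window. With local window mean $\mu$ and variance $\sigma^2$, and the
   noise power $\nu$ estimated as the image-wide mean of the local
   variances, each pixel $x$ becomes
   $\mu + \frac{\max(\sigma^2-\nu,0)}{\max(\sigma^2,\nu)}(x-\mu)$.
   Borders use symmetric padding. The filter is applied to the full image
   before masking, since the ROI is irregular.
2. **Intensity standardization.** Every pixel is transformed by
   $(x-\mu_{ROI})/\sigma_{ROI}$ using the mean and sample SD (n − 1) of
   the in-ROI intensities, so the ROI has mean 0 and SD 1. A constant ROI
   is a degenerate case and is reported as such rather than silently
   processed.
3. **Discretization.** Fixed-bin-number binning of the in-ROI standardized
   intensities into $N_g = 32$ levels over the ROI range; bin $k$ covers
   $[\min + (k-1)w, \min + kw)$ with $w = (\max-\min)/N_g$ and a closed
   top edge. Fixed-bin-number is the convention compatible with z-scored
   (dimensionless) intensities; the combination makes every texture
   feature invariant to affine rescaling of the raw image, a property the
   test suite asserts.
4. **Features.** 74 features: 17 first-order statistics on the continuous
   standardized intensities and 57 texture features on the discretized
   ROI — 25 gray-level co-occurrence (GLCM), 16 run-length (GLRLM) and 16
   size-zone (GLSZM) features. Formulas follow the IBSI reference
   definitions; all entropies use log base 2 with $0\log 0 \equiv 0$. The
   source study names its feature count but not the list, so the list here
   is fixed, documented (`feature_schema()`), and contains every feature
   the study names (`F_stat.rms`, `F_cm.joint.entr`, `F_cm.inv.var`,
   `F_cm.clust.shade`, `F_cm.info.corr.2`, `F_cm.energy`, `F_rlm.lrhge`,
   `F_rlm.glnu`, `F_szm.lze`, `F_szm.glnu`); exact parity with any
   particular extraction library's list is out of scope.
5. **Selection** (training split only): drop all-missing and all-zero
   columns (the rule is literal — constant nonzero columns stay); test
   each feature with a two-sided Wilcoxon–Mann–Whitney test; adjust with
   Benjamini–Hochberg; keep adjusted p < 0.05; then prune correlation
   iteratively — while any pair exceeds |ρ| = 0.6 (Spearman), take the
   largest-|ρ| pair and keep the member with the lower mean |ρ| against
   all features still in play.
6. **Models.** Four families — logistic regression, random forest,
   RBF-kernel SVM, gradient-boosted trees — each tuned by randomized
   search scored with stratified 5-fold cross-validated AUC on the 70:30
   training split, refit on the full training set, winner chosen by
   training AUC (exact ties broken by training sensitivity at the Youden
   cutoff). Feature scaling is z-score with mean/SD across *all* cases by
   default, which is what the emulated study describes; a leakage-safe
   train-only mode is exposed (`model_config(feature_scaling = "train")`).
7. **Evaluation.** AUC by the Mann–Whitney rank statistic (ties count ½)
   with a stratified percentile bootstrap CI (2000 replicates); the
   risk-of-malignancy cutoff maximizes Youden's J over the observed
   training risks with the rule "malignant iff risk ≥ cutoff", ties going
   to the smallest cutoff (highest sensitivity, consistent with the
   oncologic cost asymmetry); classification metrics carry normal
   approximation 95% CIs $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$
   clipped to [0, 1]; Cohen's kappa uses marginal-product chance
   agreement; calibration uses the two-step logistic recalibration
   convention — slope as the coefficient of outcome on logit(risk),
   intercept from the same regression with the slope fixed at 1 — plus a
   loess flexible curve with a bootstrap band.
8. **Delta-radiomics.** For patients with a tumor-free myometrium ROI,
   each feature becomes the ratio tumor/myometrium (missing where the
   denominator is zero or missing). Selection is a raw-p WMW screen at
   0.05, then Boruta, then the same Spearman pruning, then bidirectional
   stepwise logistic regression by AIC from the full candidate model.
   Internal validation is stratified 3-fold CV with metrics reported as
   mean ± SD over folds.

## The synthetic cohort: what it emulates, and what it does not

No public image set exists for this problem, so the generator produces a
stated world with the published cohort's structure: 100 + 100 cases, ages
drawn from class-specific normals (59 ± 13 vs 45 ± 9 years) truncated at
18, one image per case at 96 × 96 px and 0.2 mm/px (so the 5-mm cyst
exclusion is 25 px), and a tumor-free myometrium ROI for 32% of cases per
class, matching the 64/200 delta-subanalysis subset.

Image formation is multiplicative speckle over a piecewise echo field:
gamma-distributed grain smoothed to a class-specific correlation length,
over an elliptical lesion whose interior is modulated by a smooth
low-frequency heterogeneity field plus a fine-scale (σ = 1.2 px)
"structural disruption" field riding on the same amplitude. Sarcoma-like
lesions get fine grain (1.2 px), strong heterogeneity (amplitude 0.55) and
Poisson(1.0) anechoic cysts with shadows in 21%; leiomyoma-like lesions
get coarse grain (2.2 px), weak heterogeneity (0.15), Poisson(0.12) cysts
and shadows in 83%. The binary contrasts (shadow and cyst frequencies) are
taken directly from the published lesion-appearance table; the continuous
amplitudes are calibration choices, because the study reports no
quantitative per-class texture statistics.

Two non-obvious calibration facts drove the construction, and are worth
recording. First, a *smooth* heterogeneity field alone lowers co-occurrence
joint entropy: it correlates neighboring pixels. The higher entropy of
malignant echotexture is carried by fine-scale structure — hence the
disruption field, which scales with the heterogeneity amplitude so that a
lesion with amplitude 0 is exactly pure speckle (a degenerate case the
tests pin). Second, texture parameters are drawn per case from lognormal
distributions around the class means (log-SD 0.35 for grain, 0.40 for
amplitude), emulating the heavy within-class appearance overlap the study
tabulates (non-uniform echostructure in 95% of sarcomas but also 59% of
leiomyomas). Without this overlap the synthetic classes separate almost
perfectly (validation AUC ≈ 0.99), which puts the radiomics-only model at
a ceiling where adding age cannot help and the study's observed ordering
(clinical–radiomics above radiomics-only) becomes a coin flip; with it,
the radiomics-only validation AUC lands in the 0.89–0.98 range across
seeds, bracketing the study's real-data values, and the ordering holds.

What a green end-to-end test establishes is therefore that the *pipeline*
recovers a separable signal planted with the study's design and effect
structure — not that the features would separate real sarcomas from real
leiomyomas. The generator has no beamforming or attenuation physics, no
probe geometry, no operator variability, and one image per case by
construction.

## Numerical and design choices

- **Wiener noise power** is the image-wide mean of local variances, the
  classic adaptive convention; the source only names the kernel size.
- **Order of operations** (filter → z-score) follows the narrative order
  of the emulated methods; it is exposed in `preprocess_config()`.
- **Texture directions**: distance 1, four 2D directions pooled into one
  matrix per family before feature computation (pooling, not
  per-direction averaging); GLCM symmetrized by counting each pair both
  ways; size zones 8-connected; run-length runs broken by the ROI mask.
- **WMW p-values**: exact enumeration only for tie-free groups of at most
  8; otherwise the tie-corrected normal approximation with continuity
  correction (study-scale groups are large).
- **Spearman pruning ties**: the largest-|ρ| pair is processed first;
  exact ties are broken lexicographically by feature name, making the
  result independent of column order. Absolute correlation is used
  throughout (the redundancy rationale does not care about sign).
- **Boruta internals**: 500 trees per iteration, impurity (Gini decrease)
  importance, hits scored against the best shadow importance, two-sided
  binomial decisions at α = 0.05 with Holm step-down, at most 100
  iterations, undecided features reported as tentative.
- **Randomized search budgets**: 50 draws per family by default; the
  documented spaces are small and standard (forest size/mtry/depth;
  SVM cost and kernel width on log scales; boosting rounds, learning
  rate, depth, child weight, L2 penalty, subsampling). Tests and the
  acceptance script use fewer draws purely for runtime; the spaces are
  unchanged.
- **Bootstrap**: 2000 stratified case resamples, percentile intervals.
- **Degenerate inputs** are first-class: empty or constant ROIs yield
  typed errors or all-missing feature vectors with a recorded cause;
  single-gray-level ROIs make correlation-type GLCM features missing
  (0/0 guards); constant risks give a flat calibration curve rather than
  a loess crash; risks that perfectly separate outcomes set a separation
  flag on the calibration report.
- **Determinism**: a single global seed fans out to each stage through a
  stage-name hash (`derive_seed()`), so any stage can be reproduced in
  isolation; report bundles contain no wall-clock fields, and reruns are
  byte-identical.

## A note on the planted-truth selection property

The test suite includes a strict property run: plant 8 informative
features (effect sizes spread so their training p-values span roughly
1e-5 to 2e-2, matching the spread reported for the real selected
features) among 50 null features at n = 140, and ask how often the
selection chain retains *no* null feature. Benjamini–Hochberg at α = 0.05
controls the expected false-discovery *fraction*, not the probability of
admitting any null: with k informative features significant, the step-up
threshold for the best-ranked null sits near $(k+1)\,\alpha/58$, so the
chance of a perfectly clean run is around $(1-0.006)^{50} \approx 0.7$ —
regardless of how the effect sizes are chosen. A bar demanding ~19 of 20
perfectly clean runs is therefore a familywise-error expectation that the
procedure, as specified and as published, does not provide; the
corresponding acceptance test documents this and is expected to fail while
all behavioral tests of the procedure itself (agreement with a brute-force
step-up on random p-vectors, the correlation bound, planted-feature
recall, near-zero discoveries under a global null) pass.

## Known limitations

- The DICOM reader is deliberately minimal: single-frame, uncompressed
  little-endian, MONOCHROME photometric interpretations only; everything
  else is rejected with a typed unsupported-format error.
- The SVM uses a squared-hinge primal solved by L-BFGS with Platt-scaled
  risks fit on training decision values; calibrated probabilities from it
  are serviceable but cruder than a dedicated solver's.
- Pooled feature scaling (the default, faithful to the emulated study's
  description) leaks validation-set means and SDs into training; the
  train-only mode exists precisely because this is a known methodological
  weakness of the original description.
- The 74-feature list is IBSI-consistent but not formula-identical to any
  specific extraction toolkit; per-feature formula ids are in the schema.
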