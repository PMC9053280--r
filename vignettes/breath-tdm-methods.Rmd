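---
title: "Methods: from raw breath spectra to drug levels and outcome scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw breath spectra to drug levels and outcome scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`breathtdm` implements a complete analysis chain for real-time exhaled-breath
metabolomics acquired by secondary electrospray ionisation high-resolution
mass spectrometry (SESI–HRMS), in the setting of therapeutic drug monitoring
for children treated with antiseizure medication. A patient exhales five or
six times into the instrument; each exhalation appears as a plateau in the
total ion current (TIC), and every detectable ion carries a time-trace across
those plateaus. From such recordings the package derives

1. a **measurements × features matrix** of exhalation-normalised signals
   (mean nAUC),
2. a prediction of **total and free serum valproic-acid (VPA)
   concentration** from drug-related breath ions, and
3. **side-effect and drug-response risk scores** from drug-modulated
   endogenous metabolites via pathway enrichment and a one-dimensional
   principal-component score.

Because raw patient recordings cannot be redistributed, the package ships a
seeded synthetic-cohort generator whose ground truth (programmed
concentrations, outcome classes, batch factors, per-feature roles) makes
every stage testable end to end.

## 1. The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` render scan-level centroided spectra
for a cohort of subjects and visits. The model, and what each default means:

* **Exhalation pulses.** Each measurement has 5–6 pulses; a pulse is a flat
  plateau (10–20 s, drawn uniformly) with raised-cosine edges (2 s) and
  5–10 s gaps, jittered per measurement. This mirrors the plateaued TIC
  shape of prolonged exhalations.
* **Drug-related features.** Eleven mass-spectral features derived from four
  molecules — 3-heptanone (β-oxidation end product of VPA),
  4-OH-γ-lactone (ω₁-oxidation; protonated ion at m/z 143.1066),
  heptanedione and VPA itself — as protonated, sodiated and ¹³C-isotope
  ions with fixed within-molecule abundance ratios. The pulse amplitude of a
  drug feature is `a · free_vpa^b` (per-molecule ionisation coefficient `a`,
  exponent `b = 1` by default) times a per-subject metabolic-route factor
  (log-normal, SD 0.4, separate for the β- and ω₁ routes — this is what
  `pathway_activity_ratio()` recovers), times the batch factor, times
  multiplicative log-normal noise per exhalation. An isomeric breath
  background independent of VPA keeps these ions weakly present in non-VPA
  measurements.
* **Programmed concentrations.** About 54% of subjects receive VPA (the
  observed prescription fraction); subject-level total VPA is log-normal
  around 70 mg/L, fluctuating 15% between visits, and is exactly 0 for
  non-takers. The free fraction follows a saturable-binding-like curve
  `free = total · (0.07 + 0.08 · total/(total + 100))`, clipped so
  free ≤ total always.
* **Outcome classes.** Side-effect, drug-response and EEG classes
  (I vs II/III) are drawn independently per measurement with the observed
  prevalences 23/75, 26/75 and 27/75. Endogenous features mapped to the
  first two toy pathways shift **up** by `log2(1.5)` under side effects;
  features of the next two pathways shift **down** by the same amount in
  non-responders. EEG has deliberately **no** programmed effect and serves
  as the negative control.
* **Nuisance features.** White multiplicative noise around a constant level,
  never modulated by the pulse train — the targets of the
  breath-correlation filter.
* **Batch effects.** Multiplicative log-normal factors per (batch, feature),
  SD 0.3 on the log scale, with measurements assigned to contiguous batches
  as acquisition dates would.
* **Missingness.** Detection is Bernoulli per (measurement, feature):
  endogenous features are detectable with probability drawn from
  Unif(0.75, 1) (thresholded MS detection rarely yields long runs of hard
  zeros for a genuinely present metabolite), nuisance ions Unif(0.4, 1),
  drug ions 0.97 on VPA and 0.3 off VPA — the latter drives the
  80%-presence drug filter.

`simulate_feature_matrix()` renders the post-extraction nAUC matrix directly
from the identical amplitude model (per exhalation, amplitude × the
window-averaged pulse shape × noise, averaged over exhalations), which makes
hundred-cohort simulations affordable; by default it also drops the nuisance
features, emulating the stage after the breath-correlation filter. What the
generator does **not** emulate: ionisation physics, vapour–liquid
partitioning, mass-calibration drift beyond a 1-ppm jitter, isomer overlap,
and any real biochemical network structure — passing tests demonstrate that
the statistical machinery recovers programmed truth under this model, not
that the clinical findings would replicate.

## 2. Trace processing

* `detect_exhalations()` thresholds the TIC at
  `baseline + 0.3 · (max − baseline)` with the baseline at the lower decile;
  windows merged when closer than 3 s, dropped when shorter than 5 s.
  Measurements with fewer than two windows are excluded and logged as
  failed, mirroring the study's failed-measurement accounting.
* `align_scans()` is a recursive FFT cross-correlation alignment on a common
  m/z grid: each scan is shifted by the lag maximising correlation with the
  running mean reference, then refined on halved segments; circular shifts
  conserve per-scan intensity exactly. The pipeline leaves alignment off by
  default because synthetic centroids are generated mass-aligned and a
  quarter-FWHM grid at resolving power 140,000 over m/z 100–400 would be
  ~10⁶ bins; the operation exists, is tested, and can be switched on.
* `build_feature_list()` pools centroids over all measurements and takes
  kernel-density maxima in log-m/z (bandwidth in ppm; clusters split at 4
  bandwidths for scalability) as feature centroids, keeping those detected
  in ≥ 10% of measurements.
* `breath_correlation_filter()` computes, per measurement, the Spearman
  correlation between each feature trace and the 0/1 exhalation indicator
  and keeps a feature iff ρ ≥ 0.6 and Benjamini–Hochberg q ≤ 0.01 **in
  every measurement where the feature is present** (the literal reading; a
  quorum fraction is exposed for laxer designs). P-values use the
  t-reference on rank correlations for all n — the binary indicator's ties
  preclude the exact no-ties null anyway, and scan counts are in the
  hundreds. A constant trace has undefined correlation and fails.
* `compute_nauc()` integrates the trace over each window by the trapezoid
  rule with linear interpolation at the window boundaries, divides by the
  window duration and averages across windows. This makes a rectangular
  plateau of height *h* give exactly *h*, scales linearly, and converges
  under scan-rate refinement (< 0.5% change on doubling, verified).
* Presence of a feature in a measurement: at least one matching centroid in
  ≥ 25% of in-window scans. Absent nAUCs are stored as 0, the mask carries
  the distinction.

## 3. The concentration branch

`filter_drug_features()` keeps features present in ≥ 80% of VPA
measurements. Two complementary relevance rankings follow:
`rrelieff_weights()`, a regression ReliefF (k = 10 nearest neighbours by
Manhattan distance on range-scaled features, Gaussian rank-decayed
influence), and `forest_importance()`, out-of-bag permutation importance of
a bagged regression forest (all features available at every split).
`combine_and_select()` min–max scales each weight vector to [0, 1] (an
all-equal vector contributes 0.5 uniformly), averages them (mean is the
default; max and rank-mean are options), renormalises so the maximum is 1,
and selects predictors strictly above the empirical 0.1 cutoff. The
selected-count is reported, not forced to any particular number.

`combat_adjust()` removes known batch effects with the parametric
empirical-Bayes location/scale model: feature-wise standardisation against
batch-mean residuals, per-(batch, feature) location and scale estimates
shrunk to normal / inverse-gamma priors with method-of-moments
hyperparameters, adjustment, back-transformation. A single pass reproduces
the reference implementation to machine precision. Two documented
refinements: `preserve_moments` (default) enforces the model's stated
grand-mean/pooled-variance preservation exactly, cancelling an O(1/n) bias
of the raw scale step; and `shrink = FALSE` applies the un-shrunk estimates,
which removes constructed batch moments completely and is the only variant
that is *idempotent* — with shrinkage, the residual after a pass is
`(1 − s)·γ̂` with `s = n·t²/(n·t² + δ²)`, and because `t²` is estimated
across features it collapses together with the residuals, so repeated
application stalls rather than converging. This is a structural property of
empirical Bayes, not an implementation artefact.

`fit_egpr()` is Gaussian-process regression with the exponential
(Ornstein–Uhlenbeck) kernel `k(x,x′) = σ_f² · exp(−‖x−x′‖/ℓ)`:
inputs standardised by training statistics, hyperparameters by
marginal-likelihood maximisation (Nelder–Mead, 8 seeded restarts around the
median pairwise distance and the target variance, jitter ladder
1e-10…1e-6), predictions are posterior means clipped at 0 mg/L. Non-VPA
measurements train with target 0 so the model learns the full concentration
range. Agreement is summarised by `lin_ccc()`, Lin's concordance
correlation coefficient on population moments, with the conventions:
both series constant and equal → 1; exactly one constant → 0. Concordance
is reported both with and without the zero (non-VPA) test points, the
latter being the clinically relevant "real-world" view.
`screen_regressors()` cross-validates registered model families (eGPR,
ridge, bagged trees by default) under seeded folds and ranks them by mean
CV concordance.

## 4. The outcome branch

`filter_endogenous()` keeps features present in ≥ 50% of all measurements
with a coefficient of variation (sample SD over mean of nonzero values)
strictly above 30%. `differential_abundance()` runs Welch's unequal-variance
t-test per feature (the robust default when "two-sample t-test" is
unqualified) with BH correction; zero-variance groups get a df floor of 1
and a flag instead of an error. Log2 fold changes use a pseudo-count of 1%
of the matrix's median positive value. The analysis operates on raw
intensities by default, as the source workflow did; a log2 option with
min/2 imputation of zeros is provided.

Accurate-mass annotation (`annotate_mz()`) matches feature m/z to
adduct-shifted monoisotopic masses within 2 ppm, retaining all isomeric
candidates. Two enrichment algorithms then run against the pathway
database:

* `mummichog_enrichment()` scores each pathway by the hypergeometric upper
  tail of its significant-compound hits and calibrates it against draws of
  equally many features from the background (+1-corrected permutation p).
  Hit counts are integers, so the permutation statistic is discrete: the
  default conservative p (ties count as exceedances) is valid but cannot be
  exactly uniform under the null; the `randomized` tie-break is exactly
  uniform and is what calibration diagnostics should use. Pathways with no
  background hits are excluded and listed.
* `gsea_enrichment()` computes the weighted Kolmogorov–Smirnov running-sum
  enrichment score on features ranked by the signed t statistic, with a
  feature-label permutation null and a two-sided p on the normalised score.
  Weight 0 reduces to the classic unweighted statistic (verified against a
  brute-force oracle).

`select_enriched()` keeps pathways with **both** p-values strictly below
0.05. The significant metabolites of the selected pathways (BH q ≤ 0.25 by
default — the gate is configurable since no single value is canonical, and
moderate false-discovery tolerance is appropriate for a screening score)
feed `fit_outcome_score()`: columns standardised by training statistics,
PC1 of the covariance as the score direction (sign fixed by the
largest-|loading| member), orientation chosen so the positive class scores
higher, and the classification cutoff at the Youden-J optimum over
midpoints of sorted unique training scores (ties resolve to the lowest
threshold). `predict()` projects new data with the stored training
parameters only.

## 5. Numerical and design choices

* Degenerate inputs are conventions, not errors, wherever the downstream
  semantics are clear: flat TIC → no windows; constant trace → filter
  failure; constant target → zero importances; identical constant series →
  CCC 1.
* All stochastic steps (generator, permutations, restarts, folds) take
  explicit seeds and restore the caller's RNG state; identical
  (config, seed) reruns of the pipeline are byte-identical, and the run
  manifest records parameters and per-artefact MD5 hashes.
* Problem sizes used by the test-suite recovery simulations were chosen to
  make the assertions statistically stable: 100 seeded cohorts of 75
  measurements for predictor-selection stability, a 150-measurement cohort
  with a held-out third for concentration recovery, cohorts of 120
  measurements (40 subjects × 3 visits) averaged over seven seeds for the
  held-out outcome classifier, and 200 nuisance features for filter
  calibration. The held-out balanced accuracy is summarised as a mean over
  seeds because a single split of a 120-measurement cohort has a binomial
  standard error of ~0.06 on that quantity.
* The therapeutic reference ranges (total 50–100 mg/L, free 5–10 mg/L) are
  constants in `vpa_therapeutic_range` and are drawn on concordance plots.

## 6. Known limitations

* The generator's missingness is independent Bernoulli; real detection
  failures correlate with intensity and would make presence filters
  slightly informative about abundance.
* The toy pathway database has no overlap structure beyond random sharing;
  enrichment specificity on real KEGG-scale maps (hundreds of overlapping
  pathways) is a harder problem than the one tested here.
* Single-pass empirical-Bayes batch adjustment leaves a small residual by
  construction (see §3); for designs where complete removal matters more
  than shrinkage robustness, use `shrink = FALSE`.
* The headline concordances of the original clinical study are not
  reproducible from this package alone: they require the deposited raw
  patient data. The package reproduces the *method* and demonstrates
  recovery of programmed truth on synthetic cohorts.
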