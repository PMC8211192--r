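---
title: "pairwave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairwave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Motivation and model

Single-gene expression thresholds are fragile across platforms because
each sample carries its own multiplicative scaling — an additive shift on
the log2 scale. The within-sample difference of two genes cancels that
shift exactly, so a gene *pair* whose difference separates cases from
controls is a portable diagnostic feature. `pairwave` discovers such
pairs in a case/control cohort through seven stages: control-group
calibration, moderated differential expression, mixture-model gene
clustering on principal-component scores, a thresholded co-expression
network, wavelet peak detection along ordered gene tracks,
genetic-algorithm feature selection, and a small feedforward classifier.

The stages assume log2-scale intensity data, at least two samples per
group (dozens for the statistical stages to be meaningful), and no
missing values.

## Calibration

Every gene is standardized by the mean and SD of its *control* samples
(`zscore_calibrate()`), with the sample (n−1) SD denominator — the
convention of standard statistical software. Genes with zero control
variance have an undefined z-score and carry no contrast; they are
dropped with a warning rather than imputed. Note a structural
consequence used later: after calibration, the control-group mean of
every gene is exactly 0, so control-group track signals are identically
zero up to floating-point residue.

## Differential expression

`differential_expression()` computes the case-minus-control mean
difference and a two-sided moderated t-statistic with the per-gene pooled
variance shrunk toward the across-gene mean variance:

\[ \tilde s^2_g = \frac{d_0 s_0^2 + \mathrm{df}\, s_g^2}{d_0 + \mathrm{df}},
   \qquad t_g = \frac{\Delta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_0}}, \]

referred to a t distribution with df + d₀ degrees of freedom. The default
prior weight `d0 = 4` stabilizes variances in small cohorts while being
negligible at the default cohort size (df = 224); `d0 = 0` recovers the
ordinary pooled t-test exactly (verified against `t.test` and the
`limma` linear-model fit in the test suite). No multiple-testing
correction is applied: the downstream filter is the conventional raw
`p < 0.01` with `|logFC| > 1`, both strict.

The test runs on calibrated values, but a log2 fold-change threshold is
an expression-scale quantity, so when the uncalibrated matrix is
available its fold change (`logFC_raw`) is the filtered quantity. Both
scales are reported.

## Gene clustering

Genes are the observations: `pca_scree()` eigen-decomposes the covariance
of the column-centred DEG matrix; the scree elbow is the index maximizing
the discrete second difference of the eigenvalue curve (smallest index on
ties) — a simple, deterministic inflection rule. `gmm_cluster_bic()` fits
Gaussian mixtures with full per-component covariance over `k_range` and
keeps the `k` maximizing `BIC = 2·loglik − n_par·log n`. Fitting is
delegated to `mclust` (model `"VVV"`, `"V"` in one dimension), whose
hierarchical-agglomeration initialization makes the result deterministic;
no search over covariance families is performed. The pipeline clusters on
the first three component scores and scans `k = 1..7` by default — the
scale of gene-module counts the pipeline is designed around; both are
ordinary config knobs.

## Co-expression network

All unordered DEG pairs get a Pearson r and the exact t-transform p-value
(`n − 2` df). The network keeps edges with `|r| > 0.8` (strict) and
`p < 0.05`; 0.5 is the conventional screening value and remains available
via `r_min`. Node degree — how many strong partners a gene has — is the
within-cluster ordering key for the wavelet stage; genes absent from the
network have degree 0.

## Gene tracks and wavelet candidate pairs

Up- and down-regulated DEGs form separate tracks, grouped contiguously by
cluster, sorted by degree within a cluster, ties broken lexicographically
— so neighbouring genes have comparable regulatory importance and a sharp
contrast between neighbours is informative. The per-group mean of the
calibrated expression along a track is differenced
(`d[i] = s[i+1] − s[i]`, so position i names the pair (i, i+1)) and
transformed with a continuous Ricker (Mexican-hat) wavelet at scales
{1, 2, 4}; the per-position score is the maximum absolute coefficient
over scales, the significance threshold is `mean + 2·SD` of the scores
per track/group (with a 1e−8 floor so numerically-zero signals — e.g.
control tracks after calibration — yield no peaks), and peaks are strict
local maxima above it (leftmost position on plateaus). Pairs spanning a
cluster boundary are concatenation artifacts and are dropped; a pair
flagged in any of the four track/group analyses is a candidate
(an all-of mode is available), duplicates keeping the largest magnitude.

Two numerical choices deserve emphasis:

* **No smoothing by default.** An adjacent pair produces the difference
  pattern `(+u, −(u+w), +w)` concentrated on one position. A centred
  window-3 moving average maps it to `(u/3, −w/3, 0, −u/3, w/3)` — with
  a *zero* at the pair position — halving the detectable amplitude and
  displacing the score maximum. The unsmoothed difference keeps the
  spike, and the scale-1 Ricker kernel then acts as a matched filter for
  it. `moving_average()` (centred, valid-mode, odd window, default 3)
  remains available through `ma_window` for tracks with correlated
  position noise.
* **Scale set.** Scales {1, 2, 4} cover the spike itself and contrasts
  blurred over two to four track positions; larger scales mostly respond
  to cluster-level steps rather than pairs.

## Genetic-algorithm selection

Chains are bitmasks over candidate pairs. For each entry of the length
schedule (default 50%, 25%, 10% of the candidate count, annealed long to
short) a population (default 50) evolves by elitist truncation (top 10%
survive unchanged), fitness-proportional parent sampling, uniform
crossover (rate 0.9), per-bit mutation (rate 0.01) and cardinality repair
keeping chains within ±20% of the target length; a run stops after 100
generations or 20 without improvement. Elitism guarantees the best
fitness is non-decreasing, which the tests assert. Fitness is the mean
stratified k-fold (default 5) cross-validated accuracy of a
ridge-regularized least-squares classifier (`λ = 1e−3`, intercept
unpenalized) on the chain's pair-difference features — a deterministic,
closed-form learner cheap enough for the GA inner loop; the final model
quality is measured by the neural classifier, not by this surrogate.
Fitness evaluations are memoized per chain, and the fold assignment is
fixed by the seed, so identical inputs give identical results.

After the runs, *every* candidate pair is scored alone; single-pair CV
accuracy is the reported per-pair fitness and pairs above 0.5 are
selected. Scoring only best-chain members would under-report informative
pairs: once a chain reaches accuracy 1.0 the GA is indifferent to adding
another good pair, so best-chain membership is a tie-broken accident.

## Classifier

`split_half()` makes a stratified 50/50 split (seeded). `grid_search()`
evaluates activation × hidden sizes × learning rate (enumerated in that
nesting order, first point winning ties) by stratified CV **on the
training half only** — the test half never influences model choice. The
default grid spans sigmoid/relu, one or two hidden layers (10; 10–5) and
learning rates 0.01/0.1, with a shorter epoch budget (800) than the final
fit (2000), since only the ranking matters. `train_nn()` is a plain
fully-connected network with a sigmoid output unit trained by full-batch
gradient descent on cross-entropy, weights initialized from a seeded
uniform scaled by 1/√fan-in — deterministic by construction. `roc_auc()`
sweeps all thresholds, groups tied scores into single steps, and
integrates by trapezoid, which equals the normalized Mann–Whitney U
statistic (asserted to 1e−9 in tests, and cross-checked against `pROC`).

## The synthetic cohort generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes, with known ground truth:

* per-cluster latent factors with per-gene loadings ~ N(1, 0.2) create
  co-expression blocks;
* planted DE genes (default 200, half up, half down) shift by
  `de_effect` (default 3 log2 units — a strong but realistic microarray
  effect) in cases; a `de_effect_sd` knob makes effect sizes
  heterogeneous (default 0);
* each planted pair rides a shared pair-private factor (SD 1.5) plus a
  common case shift centred so that, after calibration, the two genes
  straddle the level of ordinary DE genes symmetrically
  (`±pair_effect/2` around it); each gene gets private noise
  `pair_noise_sd/√2` so the difference has SD `pair_noise_sd` exactly,
  mean `pair_effect` in cases and 0 in controls. All shared terms —
  cluster factor (at half loading), pair factor, baseline, per-sample
  shift — cancel exactly in the difference;
* each pair occupies a six-gene block of consecutive ids in one cluster:
  two flanking *decoy* twin pairs (same marginal construction, zero
  internal contrast) isolate the pair in the track ordering. Without
  them, pairs pooled into one mixture component stack adjacently and
  their alternating signal defeats peak detection; decoys also make the
  correlation structure less blocky than pure cluster blocks;
* a per-sample N(0, 0.5) shift models array scaling on the log2 scale
  (multiplicative on raw intensity).

Defaults mirror a cohort of 112 cases and 114 controls with 1500 genes.
The generator does **not** emulate probe-level effects, missing values,
heavy-tailed noise, outlier samples, or batch-by-chip structure — so
passing recovery tests demonstrate the pipeline's logic under its own
model assumptions, not robustness to everything real cohorts do.

The generator's construction departs from the most naive planting scheme
(one gene shifted, its partner untouched) deliberately: both pair genes
must pass the same-direction DE filter to be track-adjacent downstream,
and the pair must straddle the background level for the wavelet response
to peak *at* the pair rather than beside it. The half-strength cluster
loading of pair genes keeps their correlations to cluster mates safely
below the 0.8 edge threshold (so the two genes get equal network degrees
and stay adjacent under the lexicographic tie-break) while still
anchoring the pair to its cluster in component space.

## Problem sizes and reproducibility

The test suite validates each stage against independent oracles
(closed-form t-tests, `limma` fits, SVD, brute-force average linkage,
direct-convolution CWT, exhaustive subset search for the GA,
Mann–Whitney AUC, `pROC`) and runs recovery experiments at the default
cohort size (226 samples, 1500 genes) over ten seeds; end-to-end runs
take a few seconds each. One global seed fans out to per-stage seeds via
`stage_seed()` (an affine map modulo a 32-bit prime), so each stage is
independently reproducible and the whole pipeline is deterministic — the
report JSON reproduces byte-for-byte across runs.

## Known limitations

* Candidate pairs must be *adjacent* in a track: a planted pair whose
  genes end up in different mixture components, or with unequal network
  degrees, cannot be recovered at the wavelet stage (measured at roughly
  10–15% of planted pairs under default conditions). The GA stage can
  only select from what the wavelet stage surfaces.
* The per-track `mean + 2·SD` threshold includes the peaks themselves,
  so a track dense in true peaks raises its own bar.
* The moderated test assumes roughly comparable per-gene variances after
  calibration; heteroscedastic families would need an intensity-trend
  prior, which is out of scope.
* With strongly informative features the inner CV accuracies saturate at
  1.0 and many GA subsets tie; selection among tied subsets is arbitrary
  (which is why per-pair fitness is computed for all candidates).
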