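---
title: "Marker discovery for cutaneous radiation syndrome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery for cutaneous radiation syndrome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmark)
```

`radmark` is a discovery pipeline for serum protein markers of localized
radiation exposure: it simulates 2D-DIGE spot matrices and SELDI-TOF
spectra with a dose-by-day mouse design, screens features univariately,
selects stable discriminators by two resampling schemes, and scores the
resulting panels. This vignette explains the underlying models, the
tunable parameters, the numerical choices, and the limits of what the
package's own tests demonstrate.

## The simulated study

The design mirrors a dorsal-skin irradiation experiment: doses 0 (sham),
20, 40 and 80 Gy — chosen to produce erythema, dry and moist desquamation,
and necrosis respectively — with serum sampled during the latency phase at
days 3 and 7 post-irradiation, in two independent experimental series
(batches). The gel platform quantifies 941 spot features on 16 animals per
dose and day; the chip platform profiles ~120 peaks on 32 animals per dose
and day plus pooled-QC replicates.

Two kinds of planted markers encode the two clinical questions.
*Exposure* markers shift all irradiated groups by one multiplicative fold
change (triage: exposed vs not); *dose-monotone* markers multiply the
fold change per dose level (prognosis: the severity of the future lesion
tracks dose).

### Intensity model

Spot volumes and peak intensities are generated log-normally:

log x_{ijf} = mu_f + b_{series(i),f} + m_{dose(i),f} + e_{ijf}

with spot baseline mu_f ~ N(log 1000, 1), series effect
b ~ N(0, batch_sd²), planted marker effect m = k·log(fold), and residual
e ~ N(0, residual_sd²). Defaults: `batch_sd = 0.10` (a ~10% technical CV
between series, the order of the QC reproducibility of such platforms)
and `residual_sd = 0.30` (a ~30% biological CV, typical of serum protein
spot volumes). Real studies of this design rarely report their intensity
distributions or variance components; these are stated assumptions,
exposed in `dige_sim_config()`, chosen once and not tuned. The log-normal
form itself is the standard model for fluorescence volumes and ion
intensities. Dye effects (Cy3/Cy5) are folded into the series effect: the
dye-swap design cancels them in expectation, so they are not modeled
separately. Spot baselines and series effects are drawn from day-independent
substreams, so the day-3 and day-7 matrices of one configuration describe
the same spots and can be pooled.

SELDI spectra are Gaussian peaks (width 0.12% of m/z, the time-of-flight
resolution regime at these masses) on an exponentially decaying chemical
baseline plus white noise, with a per-spectrum multiplicative calibration
jitter uniform in ±0.1% — so every true peak stays a local maximum within
that fraction of its nominal mass, matching the 0.3%-of-mass cluster
window downstream. The QC pool is the peak-map mean with only technical
noise (15% CV by default, inside the 10–20% band expected of chip-array
replicates). The generator returns the latent per-sample peak intensities
so downstream stages can be checked against ground truth.

### What the generator does not emulate

No gel-image artifacts (spot overlap, streaking, spot trains from
post-translational modification), no saturation, no missing values, no
isotope/adduct structure, no m/z-dependent noise, and no correlation
between features beyond the shared series effect. Tests passing on these
simulations therefore demonstrate the *statistical machinery* — type-I
control, FDR control, selection stability, honest held-out evaluation —
not robustness to the artifacts of real gels or chips.

## Spectral preprocessing

`subtract_baseline()` estimates the baseline as the morphological opening
of the trace (rolling minimum then rolling maximum over a 200-Da window,
lightly smoothed): unlike a plain rolling minimum, the opening
reconstructs a monotone decaying baseline without a slope-proportional
offset, while peaks narrower than the window drop out of it entirely, so
apex heights survive within a few percent. Because the opening of a noisy
trace tracks the lower noise envelope, a wide running median of the
residual recentres the noise floor at zero before clipping.
`tic_normalize()` rescales each spectrum to the mean total ion current of
the set. `detect_peaks()` takes local maxima of a lightly smoothed trace
(5-point moving average, which suppresses single-point noise bumps) and
thresholds the signal-to-noise ratio; noise is estimated from the
running-median-detrended raw trace as the median of the *positive*
deviations scaled to a Gaussian sd — an estimator that stays consistent
after the zero-clipping of baseline subtraction, which would bias a plain
MAD downward, and that isolated peaks cannot inflate. The vendor
software's exact algorithms are undisclosed; these components are
documented choices with every threshold exposed.

Two-pass clustering follows the chip-platform protocol: pass one groups
peaks at S/N ≥ 2.5 by single-linkage within 0.3% of mass and keeps
clusters present in ≥ 50% of spectra; the completion pass admits clusters
from peaks at S/N ≥ 3 present in ≥ 10% of spectra. The printed protocol
writes these thresholds as "2.5%" and "3%"; they are read here as plain
S/N ratios — an S/N cut of 0.025 would accept pure noise — and remain
configurable in `cluster_params()`. The representative cluster mass is the
intensity-weighted member mean; a sample missing a member contributes the
interpolated intensity of its spectrum at the cluster mass (or 0 when
spectra are unavailable). A completion cluster falling inside the window
of a kept first-pass mass is discarded rather than merged, preserving the
invariant that adjacent cluster masses differ by more than the window.

## Univariate screen

Statistics run on log intensities; fold changes are reported on the
linear scale with the symmetric sign convention (+2 and −2 are equal
two-fold changes; exactly 1 prints "="), the irradiated or higher-dose
side in the numerator. The ANOVA is classical fixed-effects with no batch
covariate — the two series are pooled deliberately, as in the emulated
design — and the screen uses unadjusted p < 0.05, because the candidate
stage is exploratory; FDR control (Benjamini–Yekutieli, valid under
arbitrary dependence, applied over *all* features of a comparison) is
attached to the permutation test. The permutation statistic is the
absolute difference of log-group-means with labels permuted jointly
across features, p = (b+1)/(B+1), default B = 9999 (no count is given in
the protocol; 9999 makes the add-one estimate exact to three decimals).
Features with zero variance everywhere are flagged degenerate with p = 1
rather than erroring.

## Stability selection

Both engines are authored implementations of the resampling recipes:

* **PLS-DA/VIP**: 10 stratified 70/30 splits (stratification is a
  deviation from plain random sampling: at 16 controls a plain split can
  leave a training class empty), NIPALS PLS1 with 2 components (the
  component count is unstated in the protocol; 2 is the convention for
  score-plot-driven analyses and is exposed), VIP as the importance
  metric (the protocol says only that the software supplied "importance";
  VIP is the standard PLS importance, and the mixOmics implementation
  cross-checks ours in the tests). "Good" variables recur in ≥ 8/10
  draws.
* **Random Forest**: 1,000 trees per elementary analysis, mtry = 20,
  bootstrap of the full sample size, importance = mean Gini decrease
  (permutation importance was considered and rejected as default because
  the protocol's software default is Gini); 30 iterations; retention by
  top-10 recurrence count with threshold 24/30 — the protocol never
  states its cut, so 80% is a documented free parameter.

Both selectors canonicalize feature order (sorted ids) before fitting, so
results are invariant to column permutations of the input; all
randomness flows from one master seed through named substreams
(`derive_seed(seed, stage, index)`), making each repeat independently
reproducible.

An important caveat established by the package's own null experiments:
because the 10 (or 30) resamples are drawn from *one* dataset, features
whose chance association with the labels is strong in the full data recur
across resamples. On pure-null 941-feature data the PLS-DA scheme
therefore selects a small "good" set (typically 0–10 features, the
full-data top-ranked nulls) rather than none, and an argument assuming
exchangeability across repeats (which would predict an empty set with
probability ~1) does not apply. Stability selection here limits the
candidate set and stabilizes it — it is not a calibrated error-control
procedure, which is why held-out evaluation follows.

## Panel evaluation

`stepwise_lda()` does forward selection maximizing stratified 5-fold
cross-validated accuracy, stopping when no candidate improves it by more
than 1/(2n) (half a sample), ties to the earlier variable in canonical
order for determinism; commercial stepwise-LDA implementations
differ in their entry criterion, and CV accuracy is the natural
cross-validated reading. A singular within-class covariance falls back to
a ridge-regularized LDA with a warning. Note the reported CV accuracy of
a stepwise search is optimistically biased (it is a maximum over
candidates); unbiased numbers come from the held-out split.
`stepwise_logistic_aic()` is bidirectional `stats::step()` from the
intercept-only binomial GLM; perfect separation triggers a flagged
ridge-penalized refit.

ROC curves sweep the LDA discriminant value or logistic linear predictor;
the trapezoidal AUC equals the Mann–Whitney concordance with ties
half-credited (asserted against exhaustive pair counting in the tests).
Because reported AUCs of this kind of analysis rarely state which
flavor they are, `evaluate_panel()` emits all three, labeled:
resubstitution, cross-validated, and held-out test. PCA runs on centered,
unit-scaled log intensities with each component's sign fixed by its
largest-magnitude loading.

## Numerical and degenerate-input choices

Zero-variance predictors are dropped with warnings (PLS-DA, PCA); empty
candidate sets evaluate to a majority-rule baseline report rather than an
error; a zero-total spectrum, a duplicated sample id, or a comparison
referencing an undeclared design cell abort with the offending name
before any computation. TSVs carry full double precision (`%.15g`), so a
write/read round trip is lossless to ~1e-12 and pipeline manifests
(md5 of every output) are stable across identical runs.

## Problem sizes used in the test suite

The acceptance checks run at the study's feature and sample dimensions
(941 features, 16/group; 120-peak spectra, 32/group) but with Monte-Carlo
replication chosen for a single-CPU run: type-I calibration pools 5 null
datasets (4,705 tests, MC se 0.003); FDR control uses 200 replicates of a
200-feature 90%-null design; PLS-DA recovery uses 100 seeds and the
held-out-AUC check 50; the Random-Forest recovery check runs 1,000-tree
forests over 15 iterations and 15 seeds (a full 30-iteration run at more seeds
reaches the same conclusion). These sizes are package choices, not
statements about the original experiment.

## Known limitations

* The simulator's nuisance structure is simpler than real serum
  proteomes; absolute recovery rates on real data will be lower.
* Stability selection's null behavior (see above) means selected sets on
  weak data contain recurrent chance features; treat selection counts as
  audit trails, not p-values.
* Random-Forest top-10 recurrence at fold-1.5 effects and 16 + 48
  samples recovers 4/5 planted markers in only ~3 of 4 datasets even at
  full protocol scale — the forest's importance ranking is the limiting
  step at this sample size, which is why the gel-platform default
  selector is PLS-DA. The package reports raw counts so any retention threshold can be
  audited.
* No multi-class ROC, no mixed models, no spot-train aggregation, no
  protein identification: the pipeline ends at scored panels of feature
  ids.
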