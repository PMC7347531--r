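---
title: "Symbolic pattern dissimilarity for short ECGs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic pattern dissimilarity for short ECGs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiac autonomic innervation is affected early in Parkinson's disease,
before motor signs appear. Classical heart-rate-variability (HRV) summaries
of a standard 10-second ECG are weak markers of this prodromal phase: with
only a handful of beats per record, beat-to-beat statistics carry little
information. `psprecg` implements an alternative: treat the whole ECG
waveform (not just the R-R intervals) as a symbolic sequence, summarize how
its patterns evolve as a probabilistic model, and measure how *similar* a
subject's pattern model is to those of patients with established disease.
Subjects in the prodromal phase are hypothesized to sit closer, in this
pattern space, to prevalent patients than healthy controls do.

The package provides the full analysis chain — preprocessing, symbolic
pattern features, HRV characteristics, univariate statistics, a
backward-elimination logistic classifier, and a repeated k-fold
cross-validation protocol — together with a seeded synthetic cohort
generator so every stage is testable end to end without clinical data.

## The PSPR model

A record is downsampled to 8 Hz: output sample *j* is the mean of all raw
samples in the half-open window [*j*·125 ms, (*j*+1)·125 ms). A 10 s record
becomes exactly 80 values, each representing a 125 ms section of signal.
Each value is mapped to one of $n_s$ symbols by right-closed bins
(quantile bins by default, equal-width bins optionally).

For every pattern length $p = 1, \dots, n_p$ the symbol sequence is scanned
with a sliding window: each length-$p$ window with a successor is a
*context* $\pi$, weighted by its relative frequency
$w(\pi) = \mathrm{count}(\pi)/(L-p)$, and associated with the empirical
next-symbol distribution $P(s \mid \pi)$. Two records are compared at
length $p$ by

$$
D_p(A,B) \;=\; \sqrt{\sum_{\pi \in C_A \cup C_B}
  \frac{w_A(\pi) + w_B(\pi)}{2}
  \sum_{s} \bigl(P_A(s \mid \pi) - P_B(s \mid \pi)\bigr)^2 },
$$

where a model lacking $\pi$ contributes $w = 0$ and the uniform conditional
$1/n_s$. This convention keeps every stored object a probability
distribution and gives the bound $D_p \le \sqrt{2}$ (each inner sum is at
most 2 and the averaged weights sum to at most 1). The subject's feature
vector is the mean of $D_p$ to each of the reference (prevalent-disease)
records, one feature per pattern length; defaults $n_s = 9$, $n_p = 10$.

### Binning: one shared edge set

`symbolize()` estimates quantile edges from the series itself when called
alone. For *reference-based* features, however, `pspr_feature_matrix()`
defaults to a single edge set estimated from the pooled reference signals
and applied to every record. The reason is comparability: with per-record
adaptive edges, two records containing the *same* waveform pattern at
different amplitude histograms receive different symbols, almost no longer
contexts are shared between any two subjects, and all long-pattern
dissimilarities saturate at the "nothing shared" ceiling
($\sqrt{(1-1/n_s)^2 + (n_s-1)/n_s^2}$ under one-hot conditionals). Shared
edges restore cross-subject symbol semantics while quantile estimation
keeps them calibrated to the reference amplitude distribution. Per-series
quantile and uniform binning remain available options.

## Heart-rate characteristics

R peaks are detected by a fixed, documented recipe: 5–20 Hz order-2
zero-phase Butterworth band-pass, squared first difference, 150 ms
moving-average envelope, adaptive threshold at 0.4 times a rolling 95th
envelope percentile (1 s chunks, interpolated), per-run envelope maximum,
raw-signal refinement within ±50 ms, and a 250 ms refractory rule. The
threshold is signal-relative, so detected peak *times* are invariant to
amplitude scaling. The instantaneous HR series is $60/\Delta t$ between
successive peaks; its nine characteristics are mean, median, SD (sample,
$n-1$), kurtosis, skewness, min, max, range, and coefficient of variation
(percent). Conventions are fixed: skewness is the adjusted Fisher–Pearson
statistic; kurtosis is *non-excess* (normal data give 3), matching cohort
tables in which control kurtosis sits near 3. Statistics are computed
beat-wise (not on a resampled HR curve), the simplest reading of "HR as a
function of R-R distance".

## Classifier and selection

`backward_lr()` fits a logistic regression on all features (by design no
age or comorbidity covariates) and repeatedly removes the predictor with
the largest Wald p-value until all survivors satisfy
$p \le \alpha_{\mathrm{remove}}$ (default 0.05), one removal per step.
Performance is summarized as the Mann–Whitney AUC with a DeLong 95%
interval and sensitivity/specificity at the 0.5 probability cutoff.

Separated or quasi-separated fits need care: maximum-likelihood
coefficients diverge and Wald statistics collapse toward zero (the
Hauck–Donner effect), which would make backward elimination delete exactly
the strongest predictors. When a fit shows separation symptoms
(non-convergence, standardized coefficients above 15, or standardized SEs
above 10) the elimination p-values switch to drop-one likelihood-ratio
tests, which remain well behaved under separation, and the reported
coefficients come from a ridge-stabilized fit with an escalating penalty
($10^{-6}$ to $10^{2}$); if even the strongest penalty stays degenerate the
result is flagged `separable`. A fixed tiny penalty was tried first and
rejected: it leaves the Wald collapse fully intact, and no intermediate
penalty level is simultaneously stable and calibrated.

## Cross-validation protocol

`cv_curve()` sweeps the number of folds $k$ from 2 to 24; for each $k$ it
performs 100 random re-splits. Each re-split partitions subjects into $k$
*stratified* folds — plain random splitting at $n = 50$ and $k$ up to 24
frequently produces one-class test folds and undefined AUCs, so
stratification is the minimal repair, with remainder folds complemented
between classes so total fold sizes stay balanced. Feature selection is
re-run inside every training split (the leakage-safe protocol). The $n$
out-of-fold probabilities of one re-split are pooled into a single AUC;
per $k$ the curve reports their mean with the normal interval
mean ± 1.96·SD/√repeats (an interval for the mean over re-splits; with one
repeat it collapses to the value).

A known property of this protocol, visible in the package's own null
experiments: on data with *no* signal, repeated CV with per-split stepwise
selection does not center exactly on AUC 0.5. Selected noise features
over-fit their training folds, and because the dataset is fixed, their
training-fold association systematically anti-correlates with the held-out
folds; pooled out-of-fold AUC then sits a few points *below* 0.5, further
than the (very narrow) across-repeat interval is wide. The interval
quantifies re-splitting noise only — not cohort sampling noise — and should
not be read as a significance test against 0.5.

## The synthetic cohort generator

No public ECGs exist for this study design, so the generator is an
explicit stand-in, not a physiological simulator. It emulates the
statistical structure the analysis relies on:

* **Design**: 25 controls, 25 prodromal-like, 10 prevalent-like subjects;
  10 s single-lead records at 500 Hz.
* **Rhythm**: instantaneous HR i.i.d. normal, truncated at 20 bpm,
  converted to RR intervals. Group centers follow the published cohort
  summaries (mean HR 65.30/64.50/68.24 bpm; within-subject HR SD
  2.65/3.87/1.20 bpm for control/prodromal/prevalent). Subject-level
  spread is 3 bpm (SD) for the HR mean and a gamma with SD 2 bpm for the
  HR SD. The cohort tables' confidence intervals would imply a much larger
  between-subject spread (≈ 8–11 bpm on mean HR); that choice was examined
  and rejected for the default because it is partly an artifact of
  digitization noise and outliers and it drowns every waveform-pattern
  effect; the spreads are configurable.
* **Morphology**: each beat is a sum of five Gaussian wavelets (P, Q, R,
  S, T) with textbook-plausible amplitudes and widths.
* **Disease signature**: records are split into 5 s segments. A fraction
  `morph_delta` of segments (0 / 0.5 / 1.0 by group) carries the shared
  signature: a time-locked 1.6 Hz baseline oscillation (0.22 mV, phase on
  the symbol grid) plus a period-2 beat-to-beat T-wave amplitude alternans
  (depth 0.35) — T-wave alternans being the classic repolarization
  instability marker. Non-signature segments carry a subject-random slow
  oscillation (0.5–1.2 Hz) and a smooth respiratory-like T modulation of
  equal depth, so all groups have comparable within-record variability and
  value histograms; the groups differ in how much of their pattern
  structure is *shared with the references*, which is exactly what the
  dissimilarity features measure. Grading the signature by duty cycle
  rather than amplitude is deliberate: a half-amplitude pattern quantizes
  to different symbols than the reference's full-strength pattern and
  shares no contexts with it, whereas a half-duration pattern shares them
  over half the record, making feature means decrease monotonically in
  `morph_delta`.
* **What the signature avoids**: R-wave amplitude is never modulated (an
  R alternans would push alternate beats under the fixed detector
  threshold and corrupt the HR series), and no RR-interval structure is
  added, so the signature is invisible to all nine HR characteristics by
  construction.
* **Nuisance realism**: per-subject log-normal calibration scale (SD
  0.15, emulating amplitude calibration differences across digitized paper
  records) and 0.02 mV additive white noise. The calibration jitter also
  keeps the default cohort out of the perfectly-separable regime, where
  stepwise logistic selection is statistically degenerate.
* **Seeding**: every subject's seed is hashed from
  (global seed, group, index); identical specs reproduce byte-identical
  cohorts.

What the generator does **not** emulate: 12-lead geometry, arrhythmias,
conduction blocks, infarction morphologies (the study design excluded such
subjects), QT/HR coupling, respiration-locked RR modulation, or any
validated electrophysiological model of prodromal disease. Passing tests
on this cohort demonstrate that the pipeline recovers a planted
group-graded pattern signature under realistic rhythm and calibration
noise — not that real prodromal ECGs carry such a signature.

## Numerical and procedural choices

* 500/8 is not an integer, so 125 ms windows alternate between 62 and 63
  samples; windows are time-based and half-open, and only complete windows
  are emitted.
* A constant series under quantile binning collapses all edges; it maps to
  all-zero symbols by convention (documented degenerate case).
* Dissimilarities of a model to itself are exactly 0; unseen contexts use
  the uniform conditional, preserving the $\sqrt 2$ bound.
* Grid-search ties resolve to the smaller $n_s$, then smaller $n_p$
  (parsimony, determinism). Scoring is in-sample by default; any
  fit-and-score callback can be substituted.
* Group comparisons route by a per-group KS normality screen (plain KS
  with estimated parameters — conservative, as documented) to ANOVA or to
  Mann–Whitney / Kruskal–Wallis; two-tailed, α = 0.05, and deliberately no
  multiplicity correction (matching per-test reporting conventions in the
  clinical literature; a correction flag exists).
* For constant HR series the SD-based moments are undefined and returned
  as `NA`; the degenerate case cannot arise from the generator, whose HR
  SD is floored at 0.05 bpm.
* The test suite runs the full study shape where the property needs it
  (25/25/10 cohorts, $k$ = 2..24, 100 CV repeats for the headline
  analysis) and reduced sizes (small cohorts, 2–25 repeats) for plumbing
  properties; each test states its sizes explicitly.

## Known limitations

* The dissimilarity is a semi-metric (no triangle inequality is claimed).
* At pattern lengths much longer than the oscillation period and beat
  spacing, contexts become record-specific and features saturate near the
  unshared ceiling; the informative lengths on 80-symbol records are the
  short-to-middle ones. This mirrors the sparsity of 10 s records rather
  than a removable implementation detail.
* The KS screen with estimated parameters is conservative; borderline
  features may route to ANOVA that a Lilliefors-corrected screen would
  send to the nonparametric branch.
* The CV interval is a re-splitting interval conditional on one cohort;
  see the protocol section for why it can sit entirely below 0.5 on null
  data.
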