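---
title: "Estimating the post-mortem interval from pericardial-fluid metabolomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the post-mortem interval from pericardial-fluid metabolomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfpmi)
```

## The problem

The post-mortem interval (PMI) — the time elapsed since death, in hours — is
one of the hardest quantities in forensic practice to estimate reliably. The
metabolome of a confined, slowly exchanging biofluid such as pericardial fluid
changes progressively after death: membrane phospholipid degradation releases
choline and ethanolamine, protein breakdown releases glycine, purine
catabolism consumes hypoxanthine, and, at late intervals, bacterial
co-metabolism floods the fluid with formate, trimethylamine, propionate and
butyrate. A quantified ¹H NMR metabolite table (samples × metabolites,
concentrations in mM) therefore carries a usable PMI signal, and this package
implements the multivariate workflow to extract it.

Two features of real autopsy cohorts shape the whole design:

* **Age is a confounder.** In consecutive judicial autopsies, subject age and
  PMI are typically correlated (in the packaged 24-autopsy cohort,
  r = 0.35), so a naive regression can silently learn age-related metabolome
  differences instead of post-mortem chemistry.
* **Late PMIs behave non-linearly.** Above roughly 100 h the bacterial surge
  products dominate and a linear model calibrated across the full range
  degrades; restricting the modelling window is the pragmatic answer.

## The constrained latent-variable model

The core regression is an orthogonally constrained PLS (oCPLS2) of autoscaled
concentrations **X** (n × p) on PMI y, with a constraint matrix **Z** whose
columns are the centred confounders (age alone by default). Each predictive
weight vector **w** is the usual PLS covariance direction **Xᵀy** projected
into the null space of **ZᵀX**, so the score **t = Xw** satisfies **Zᵀt = 0**
*exactly* — not approximately. After each component, **X** (and y) are
deflated in the standard NIPALS fashion and the projector is rebuilt from the
deflated matrix, so every retained score is orthogonal to every constraint
column to machine precision. Because the fitted values live in the span of the
scores, the calibrated PMI estimates have exactly zero sample correlation with
age: the model cannot encode the confounder.

Non-predictive components are handled OPLS-style *before* the predictive
regression: a component capturing systematic X-variation orthogonal to both
the response and the constraint is extracted and removed, and the predictive
model is fitted to the filtered matrix. One non-predictive plus one predictive
component gives predictions equivalent to two predictive components (the
usual OPLS equivalence); the split exists for interpretability, separating
"structure the model uses" from "structure the model discards".

An interpretation caveat that our own simulations make vivid: when the
response correlates with the confounder, a metabolite that depends *only* on
the confounder can receive a **larger** weight (and VIP) under the constraint
than without it, because it is the best available instrument for cancelling
the confounder component carried by the genuine markers — exactly as a
confounder proxy takes a non-zero coefficient in an adjusted linear
regression. The constraint guarantees confounder-free scores and fitted
values; it does not guarantee small weights on confounder-linked metabolites,
and VIPs must be read accordingly.

## Model assessment

* **R² and SDEC** describe calibration; SDEC is the root-mean-square
  calibration error in hours (denominator n, the chemometrics convention).
* **Q² and SDECV** come from repeated 5-fold cross-validation (20 repetitions
  by default). Within every training fold the autoscaling statistics,
  constraint centring and model are recomputed from scratch and applied to
  the held-out fold; Q² = 1 − PRESS/TSS is pooled per repetition and averaged
  across repetitions, as is SDECV = √(PRESS/n).
* **SDEP** is the same RMSE computed on an untouched test set.
* The **randomization test** permutes y (keeping **X** and **Z** aligned),
  reruns the full fit-and-cross-validate pipeline at the fixed component
  configuration, and reports p = (1 + #{permuted ≥ observed})/(1 + N)
  separately for R² and Q². It is the guard against an over-fitted latent
  model. The default is 999 permutations; Monte-Carlo calibration
  experiments in the test suite use 99 per replicate so that 100 outer
  replicates remain tractable.

Component counts are chosen by maximizing the cross-validated Q² over a small
grid, ties broken toward fewer components.

## Variable selection

Relevant metabolites are found by stability selection: 200 subsamples are
drawn by Binary Matrix Sampling — independent Bernoulli(0.7) masking of both
rows and columns — and within each subsample a VIP-guided backward
elimination (drop everything with VIP < 1, refit, keep the subset with the
best cross-validated Q² along the path) returns one "best subset". A
metabolite's selection count is then compared with a size-matched
random-choice null: if subsample s chose a subset of size k_s among p_s
available predictors, a null metabolite is selected there with probability
k_s/p_s, and the total count is Poisson-binomial across subsamples, evaluated
exactly by dynamic-programming convolution. One-sided p < 0.05 flags the
metabolite as relevant.

A known property of this procedure at small n, documented here deliberately:
the random-choice null assumes independent selection across subsamples, but
subsamples share ~70% of the same individuals, so a metabolite that
*spuriously* correlates with PMI in a particular cohort (at n ≈ 20,
|r| up to ~0.45 arises by chance) is selected consistently across that
cohort's subsamples and can be flagged. In our synthetic-cohort experiments
any single truly PMI-stable metabolite is falsely flagged in roughly 15–20%
of cohort draws at α = 0.05, a couple of times its nominal level. This is a
property of the published procedure, not of its implementation; it is
consistent with such analyses reporting double-digit "relevant" panels from
50-metabolite tables, and it is why the per-metabolite relevance flags should
be read as a ranking with an approximate error rate rather than as calibrated
hypothesis tests.

## Univariate profiles

For each metabolite, a two-factor ordinary least-squares regression of
concentration on PMI and age gives the reported p-value (two-sided t-test on
the PMI coefficient); the reported r is the Pearson correlation between the
age-corrected concentration (conc\*, the OLS residual of concentration on
age) and PMI. By the Frisch–Waugh theorem the two views agree: the MLR PMI
coefficient equals the slope of conc\* on age-residualized PMI, and the test
suite asserts that identity to 1e-9. Significance is flagged at 0.05, and a
0.10 threshold gates which profiles are displayed. Benjamini–Hochberg
adjusted p-values are emitted as supplementary output but never gate
relevance, matching the raw-p reporting convention of this literature.

## Exploratory diagnostics

PCA (SVD on the autoscaled table, component signs fixed by making each
component's largest-magnitude loading positive) supports two outlier tests:
Hotelling's T² in the retained score space against its F-distribution limit,
and the Q residual (squared distance from the model plane) against the
Jackson–Mudholkar limit. The number of retained components defaults to those
reaching 80% cumulative explained variance, capped at 5.

## The synthetic cohort generator

No raw concentration tables from real cohorts are distributed, so the
package ships a generator whose defaults emulate the study conditions the
analysis assumes, with exported ground truth for every metabolite:

* **Design**: 24 individuals; PMI uniform on [16, 170] h (or the packaged
  empirical design); age drawn jointly with PMI through a Gaussian copula
  targeting Pearson r = 0.35 (latent correlation 2·sin(πr/6), exact for the
  uniform margins); sex Bernoulli(0.7 male); sex has no effect on
  concentrations.
* **Panel** (50 metabolites): choline, ethanolamine, glycine rising linearly
  with PMI and hypoxanthine falling (effect sizes set so their age-corrected
  correlations with PMI are ≈ 0.5–0.56 at the ≤ 100 h design — the
  moderate-to-strong profiles expected of these markers); formate,
  trimethylamine, propionate, butyrate as hinge ("surge") terms active only
  above 100 h; 3-hydroxybutyrate as the PMI-stable control; ethanol
  (U-protocol only) and caffeine as exogenous; 39 null fillers with typical
  biofluid baselines. The hinge onset (100 h) is configurable; a linear slope
  plus hinge is the simplest form consistent with "flat below, rising above".
* **Noise**: concentrations are latent · exp(ε) with σ = ln(1 + CV).
  Biological variability is split into a global per-individual intensity
  factor (CV 0.30; fluid dilution and decomposition stage, common to all
  metabolites) and a per-individual per-metabolite effect (CV 0.30), both
  shared between the paired U/LLE aliquots; technical noise (CV 0.15) is
  drawn independently per protocol. Negative latent values are clipped at
  zero (hypoxanthine can bottom out at very long PMIs).

What this emulates well: the paired-protocol concordance (U/LLE correlations
above 0.9 for metabolites carrying latent structure, ≈ 0.87 for pure-noise
fillers), the age confounding, the late-PMI non-linearity, and the
approximate detectability of the four markers. What it does not emulate:
peak-overlap quantification errors, cause-of-death effects, non-uniform PMI
sampling, and any real between-metabolite correlation beyond the global
intensity factor. A deliberate design trade-off: with the technical CV fixed
at 0.15, pushing the structureless fillers' paired correlation above 0.9
would require so much shared biological noise that raw-scale marker–PMI
correlations cap near 0.5 and the selection experiments lose their power;
the defaults favour realistic marker detectability.

## Study orchestration

`run_study()` reproduces the full design: exogenous exclusion → cohort
summary → PMI-stratified 18/6 split (4 equal-frequency PMI bins, test samples
allocated proportionally with largest-remainder rounding, re-drawn until the
training set matches the cohort sex ratio within one sample and the cohort
mean age within half an SD) → per protocol (U and LLE are analysed
separately, never pooled) and per PMI range (full, and ≤ 100 h reusing the
full-range split minus the late samples): autoscale on training, select
components, fit, cross-validate, randomization-test, predict the held-out
samples, stability-select, and profile. All randomness flows from one seed
through named streams (metadata, concentrations, folds, permutations,
subsampling, split), so a report is reproducible byte-for-byte. Reporting
precision follows the field's convention: R²/Q² to 3 decimals, errors to
whole hours, correlations to 2 decimals.

## Numerical choices and degenerate inputs

* Autoscaling uses the n − 1 SD; zero-variance columns are dropped with a
  warning (scaling is undefined for them); a single-row table can only be
  scaled against a reference.
* The null-space projection uses an SVD pseudo-inverse with a relative
  tolerance of 1e-12; a constraint with as many effective columns as
  predictors is an error.
* Requested components beyond the available rank raise errors rather than
  returning silent zeros; CV repetitions whose training fold has constant y
  are discarded with a warning.
* BMS masks with fewer than 8 rows or 2 columns are redrawn; subsample
  columns that are constant within the subsample are treated as unavailable
  there.
* The Poisson-binomial DP is exact; the test suite cross-checks it against
  full enumeration up to 15 subsamples.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run entirely on synthetic cohorts at
the study's own scale (n = 24, p = 50). Monte-Carlo experiments use 100
replicates for calibration checks (99 permutations each), 25 replicates for
stability-selection recovery (200 subsamples each), 100 replicates for
held-out prediction, and 50 for the range-restriction comparison; oracle
comparisons use 50 random small instances. These sizes give binomial
standard errors comfortably inside the asserted bands while keeping a full
run in the minutes range on a single core.

## Known limitations

* The stability-selection relevance flags are anticonservative at this
  sample size (see above); the package reports them faithfully.
* The oCPLS2 literature admits several deflation/post-transformation
  variants; this implementation commits to the contract (exact
  score–constraint orthogonality, OPLS-style non-predictive filtering,
  NIPALS deflation) rather than to any single historical variant's
  internals. With an empty constraint it reduces exactly to textbook PLS1,
  which the test suite verifies against an independent reference
  implementation.
* Late-PMI non-linearity is handled by range restriction only; no nonlinear
  latent model is provided.
* Predictions are point estimates; no per-case predictive intervals are
  attempted, matching the held-out-set validation design.
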