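# pfpmi

Estimation of the post-mortem interval (PMI) from quantified ¹H NMR
metabolite concentrations of human pericardial fluid.

After death the pericardial-fluid metabolome changes progressively —
choline, ethanolamine and glycine rise, hypoxanthine falls, and bacterial
surge products (formate, trimethylamine, propionate, butyrate) appear at
late intervals — so a samples × metabolites concentration table carries a
recoverable PMI signal. The catch in real autopsy cohorts is confounding:
subject age correlates with PMI, and an unconstrained regression happily
learns age instead of post-mortem chemistry. `pfpmi` is built for forensic
and metabolomics researchers who want that analysis as a tested, reproducible
pipeline.

## What is inside

The modelling core is an **orthogonally constrained PLS regression
(oCPLS2)**: every predictive weight vector **w** is the PLS covariance
direction projected into the null space of ZᵀX, so each score **t = Xw**
satisfies Zᵀt = 0 *exactly* for the constraint columns Z (centred age by
default) and the latent space cannot encode the confounder. Around it:

* repeated 5-fold cross-validation (Q², SDECV) with in-fold rescaling,
* randomization (permutation) tests for R² and Q²,
* component selection by cross-validated Q²,
* **stability selection**: VIP-guided backward elimination over 200 Binary
  Matrix Sampling subsamples, with an exact Poisson-binomial test of each
  metabolite's selection count against a size-matched random-choice null,
* age-corrected univariate profiles (two-factor MLR; r of conc\* vs PMI),
* PCA with Hotelling T² and Q-residual outlier tests,
* a PMI-stratified 18/6 training/test split with demographic matching,
* a synthetic cohort generator with exported ground truth (paired
  ultrafiltration/liquid–liquid-extraction tables, realistic noise
  structure, a PMI–age correlation of 0.35), and
* the printed 24-autopsy cohort metadata table as a packaged fixture.

Performance metrics follow the chemometrics conventions: SDEC/SDECV/SDEP are
root-mean-square errors (hours) in calibration, cross-validation and external
prediction; Q² = 1 − PRESS/TSS.

## Worked example

```r
library(pfpmi)

# a synthetic cohort at the study design: 24 autopsies, PMI 16-170 h,
# paired U/LLE tables, 50-metabolite panel
cohort <- simulate_cohort(cohort_config(seed = 1))

run <- run_study(cohort$tables, cohort$metadata,
                 n_permutations = 199, stability_subsamples = 100, seed = 1)
tidy(run)
```

```
#> # A tibble: 4 x 14
#>   protocol range  max_pmi n_train n_test n_predictive n_non_predictive    r2
#> 1 U        full       Inf      18      6            1                1 0.755
#> 2 U        le_100     100      12      4            2                1 0.909
#> 3 LLE      full       Inf      18      6            2                1 0.881
#> 4 LLE      le_100     100      12      4            2                0 0.846
#>      q2  sdec sdecv  sdep  p_r2  p_q2
#> 1 0.243    22    39    33 0.105 0.005
#> 2 0.382     7    18    15 0.555 0.005
#> 3 0.602    16    28    29 0.12  0.005
#> 4 0.575     9    15    16 0.155 0.005
```

Read: on the full 16–170 h range the held-out prediction error (SDEP) is
29–33 h; restricting to PMI ≤ 100 h — below the bacterial-surge onset —
roughly halves it to 15–16 h, the behaviour this workflow is designed to
expose. The randomization p-values for Q² sit at their lower bound (1/200):
the cross-validated predictive power is not explained by overfitting.

```r
# which metabolites drive the model?
dplyr::filter(run$stability, range == "le_100", protocol == "U", relevant)
#> 12 metabolites flagged; glycine, ethanolamine and hypoxanthine are among
#> them with selection frequencies 0.57-0.70 against null frequencies ~0.45-0.49.
#> Expect some PMI-null metabolites to ride along: at n ~ 20 the random-choice
#> null is anticonservative (see the methods vignette), which is why these
#> flags are best read as a ranking rather than calibrated tests.

# age-corrected univariate view (the per-metabolite r and p table)
dplyr::arrange(dplyr::filter(run$profiles, protocol == "U", range == "full"),
               p)

# plots
autoplot(fit_pca(autoscale(exclude_exogenous(cohort$tables$U)), 2),
         metadata = cohort$metadata)     # score plot, PMI-coloured
plot_profiles(exclude_exogenous(cohort$tables$U), cohort$metadata)
```

The packaged cohort metadata reproduce the printed demographics exactly:

```r
cohort_summary(load_cohort_fixture())
#>       n n_male n_female age_mean age_sd pmi_mean pmi_sd pmi_age_r pmi_age_p
#> 1    24     17        7     50.9   20.8     70.2   45.6     0.346    0.0977
```

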