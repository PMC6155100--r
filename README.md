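# xpconn

Cross-paradigm functional connectivity traits and network-based
statistics, with a calibrated synthetic multi-paradigm cohort generator.

## The problem

Multi-paradigm fMRI studies of psychosis risk collect several scans per
subject (rest and tasks) and ask whether some connectivity alteration is
*state-independent*: present whatever the brain is doing, graded with
clinical risk, correlated with symptoms, and transferable to independent
clinical samples. `xpconn` implements that analysis end to end for anyone
working with node time series or precomputed connectomes:

* **Connectivity** — nuisance regression (task regressors, tissue
  signals, motion expansion, frame-wise displacement), zero-phase
  Butterworth filtering (rest band-pass 0.008–0.1 Hz, task high-pass
  0.008 Hz), pairwise Pearson correlation, canonical edge vectorization.
* **Trait extraction** — per subject, a covariance PCA across the
  paradigm-wise edge vectors (edges are observations, paradigms are
  variables). The first-component edge scores are the subject's
  *cross-paradigm connectivity* trait matrix; loadings and variance
  explained are reported per subject.
* **NBS** — edge-wise covariate-adjusted F tests (age, sex, IQ, site,
  mean FD, antipsychotic dose by default), a primary p threshold,
  connected components among suprathreshold edges, and family-wise-error
  p values from the permutation distribution of the maximal component
  statistic, permuting reduced-model residuals (Freedman–Lane).
* **Post-hoc battery** — network means, omnibus/linear-trend ANCOVA,
  covariate-adjusted pairwise contrasts (Bonferroni), Cohen's d, Spearman
  correlations with symptoms and months-to-conversion, a random-edge
  specificity permutation, and ROC transfer of a discovered mask to an
  independent cohort with a permutation p for the AUC.
* **Synthetic cohorts** — `generate_cohort()` draws multi-paradigm
  cohorts with a shared per-subject latent architecture, a planted
  hyperconnected subnetwork with graded group effects (calibrated in
  Cohen's d units), covariate confounding, and phenotypes coupled to the
  planted-network strength, so the whole pipeline is testable without
  clinical data.

The methods vignette (`vignettes/cross-paradigm-connectivity.Rmd`)
documents the model, the generator's assumptions and defaults, and the
numerical choices.

## Worked example

```r
library(xpconn)

res <- run_pipeline(list(synth = list(seed = 7),
                         threshold_p = 0.001,
                         n_permutations = 1000, seed = 7))
glance(res$nbs)
#> # A tibble: 1 × 8
#>   n_components observed_max min_fwe_p winning_edges n_permutations threshold_p
#>          <int>        <dbl>     <dbl>         <int>          <int>       <dbl>
#> 1            8           13  0.000999            30           1000       0.001

res$posthoc$reports[, c("test", "statistic", "value", "p", "n")]
#> # A tibble: 7 × 5
#>   test                             statistic  value        p     n
#>   <chr>                            <chr>      <dbl>    <dbl> <int>
#> 1 ancova_omnibus:network_mean      F         36.4   5.24e-12    90
#> 2 ancova_linear_trend:network_mean t          8.58  5.01e-13    90
#> 3 pairwise:nonconverter-control    t          3.93  1.77e- 4    90
#> 4 pairwise:converter-control       t          8.51  7.25e-13    90
#> 5 pairwise:converter-nonconverter  t          4.56  1.80e- 5    90
#> 6 correlation_spearman             rho        0.442 1.28e- 5    90
#> 7 correlation_spearman             rho       -0.498 5.14e- 3    30
```

Reading this output: the default synthetic cohort has 90 subjects in
three ordered outcome groups (healthy control < non-converter <
converter) over five paradigms. The NBS finds eight suprathreshold
components; the four largest survive FWE correction and together form a
30-edge winning mask (Jaccard 0.71 against the planted truth in this
run). The mask's mean cross-paradigm connectivity shows a strong graded
group effect (omnibus F = 36.4; increasing linear trend t = 8.6), is
largest in converters (pairwise t = 8.5 versus controls; Cohen's
d = 0.68), correlates positively with the disorganization symptom score
(Spearman rho = 0.44, n = 90) and negatively with months-to-conversion
among converters (rho = −0.50, n = 30). The per-subject first principal
component explains 70% of the connectivity variance across paradigms on
average in this cohort.

Individual stages are plain functions when you need them separately:

```r
cohort <- generate_cohort(synth_config(seed = 7))
trait  <- cohort_trait_edges(cohort)          # subject x edge PC1 scores
nbs    <- nbs_test(trait$trait, cohort$design,
                   covariates = c("age", "sex", "iq", "site", "fd", "dose"),
                   threshold_p = 0.001, n_permutations = 1000, seed = 7)
scores <- network_mean(trait$trait, nbs$winning_mask)
```

`plot_group_means()`, `autoplot()` on `nbs_result` and `roc_result`
objects give the standard figures.

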