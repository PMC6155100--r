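---
title: "Cross-paradigm connectivity traits and network-based statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-paradigm connectivity traits and network-based statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpconn)
```

## The problem and the model

Functional MRI studies of psychosis risk acquire several paradigms per
subject — rest, working memory, episodic memory, emotion processing — and
each paradigm yields one whole-brain functional connectome: a node-by-node
matrix of Pearson correlations between the (noise-corrected, filtered) node
time series. Paradigm-specific effects dominate any single matrix, but a
large share of connectivity structure is stable within a subject across
paradigms. xpconn implements an analysis built on that observation:

1. **Connectivity.** For every scan, node time series are residualized on
   an intercept plus the supplied nuisance regressors (task regressors,
   tissue signals, the 24-parameter motion expansion, frame-wise
   displacement), optionally band-pass filtered (rest: 0.008–0.1 Hz) or
   high-pass filtered (task: 0.008 Hz), and correlated pairwise. The
   operations are applied in that order (regression, then filtering, then
   correlation).

2. **Trait extraction.** Per subject, the paradigm-wise edge vectors are
   arranged as edges-by-paradigms and decomposed by covariance PCA
   (columns mean-centered, not scaled). The orientation matters: with
   edges as observations the fit produces one loading per paradigm and one
   first-component score per edge — the "cross-paradigm connectivity"
   trait matrix. The reverse orientation could not report per-paradigm
   loadings. The component sign is fixed so scores correlate
   non-negatively with the across-paradigm mean edge value, making "higher
   score = stronger shared connectivity" interpretable in every subject;
   without such a convention the per-subject PC sign is arbitrary and group
   analyses would be meaningless.

3. **Network-based statistic (NBS).** Edge-wise covariate-adjusted F tests
   of the group factor (extra sum of squares between the covariate-only and
   the full model), a primary threshold on the edge-wise p value,
   connected-component formation among suprathreshold edges, and a
   family-wise-error-corrected p value for each component from the
   permutation distribution of the maximal component statistic.
   Because covariates are in the model, naive label permutation is not
   valid; permutation follows Freedman–Lane: residuals of the reduced
   (covariate-only) model are row-permuted, the full model is refitted, and
   the identical threshold/component procedure is applied.

4. **Post-hoc battery.** Mean connectivity over a discovered mask,
   omnibus and ordered linear-trend ANCOVA, covariate-adjusted pairwise
   contrasts with Bonferroni correction, Cohen's d, Spearman correlations
   with symptom scores and months-to-conversion, a random-edge specificity
   permutation (random same-size edge sets, group test on each set mean),
   and ROC transfer of a mask to an independent cohort with a label-shuffle
   permutation p for the AUC.

## Tunable parameters that matter

* `threshold_p` (NBS primary threshold, default `0.001`): no canonical
  value exists in the field; the default is the common choice for
  focal effects. The threshold changes *which* networks can be found
  (sparse/strong vs extended/weak), not the validity of the FWE control —
  sweep it when results are ambiguous.
* `statistic` (`"extent"` or `"intensity"`): component size as an edge
  count, or as the sum of suprathreshold F excess. Extent matches how
  network sizes are conventionally reported. Note a statistical subtlety
  quantified below: at sparse thresholds the extent null is a small-integer
  distribution with heavy ties, and the resulting FWE is conservative
  (observed around 0.005 at a nominal 0.05 in our calibration runs);
  the intensity null is continuous and calibrates near the nominal level
  (0.05 in the same conditions). Calibration-sensitive work should use
  intensity; reporting "k edges" should use extent.
* `n_permutations`: at least a few hundred for stable FWE p values near
  0.05; p values use the +1 correction and can never be exactly zero.
* Covariates: age, sex, IQ, site, mean FD, antipsychotic dose by default —
  the same set for the edge-wise model and every post-hoc ANCOVA.
  Categorical covariates are dummy-coded dropping the first level.

## The synthetic cohort generator

`generate_cohort()` exists so every downstream stage is testable without
clinical data. It emulates the *statistical* structure the analysis
assumes; it is not a biophysical simulator.

Per scan, a covariance is built that is positive semi-definite by
construction:

* a cohort-level low-rank factor model (base loadings `W0` plus a
  diagonal) gives the background connectome;
* subject topography and paradigm state perturb the *loadings*
  (`W_s = W0 + sqrt(f) w_a Xi_s`, `W_sp = W_s + sqrt(1-f) w_b Xi_sp`),
  so every matrix stays a valid covariance; `f` is the shared-variance
  fraction;
* the planted subnetwork enters as symmetric signal mixing between its
  node pairs (`Sigma' = M Sigma M`, `M = I + Theta`) — a congruence
  transform, hence valid for any mixing weight, with a natural
  interpretation as shared drive between circuit nodes. The baseline
  weight puts the planted edges at a positive connectivity level
  (`mask_base_z`, default Fisher-z 0.4), mirroring the observation that
  circuit connectivity is positive in all groups and only its *strength*
  differs;
* subject strength combines covariate effects (motion, dose, age) and a
  residual trait; group shifts are calibrated so the realized Cohen's d of
  the mean planted-edge connectivity matches `effect_sizes`. Because the
  strength-to-Fisher-z response is concave, the calibration numerically
  inverts the population-averaged response on the actual per-scan loadings
  rather than using a linear slope, and works on the observed scale
  (including the analytic attenuation `1/(1 + noise_sd^2)` caused by
  measurement noise);
* node time series are drawn from each scan's correlation structure using
  one innovation sequence per subject shared across paradigms. This makes
  finite-scan sampling error behave as a stable subject-level component
  and gives an exact identity — with `shared_variance_fraction = 1` and
  `noise_sd = 0` all paradigms of a subject yield bit-identical
  connectivity matrices. Real scans have independent sampling noise per
  run; this is one of the deliberate idealizations listed below.

### Default conditions and why

* `n_nodes = 60` — desk-scale; the full 270-node atlas is supported but
  memory- and time-hungry.
* `n_paradigms = 5`, `timepoints = 240` at TR 2 s — five paradigms of
  eight minutes, matching a typical multi-paradigm battery.
* `group_sizes = 30/30/30` (control < non-converter < converter),
  `effect_sizes = (0, 0.5, 1)` — a graded "risk" effect with the
  highest-risk group strongest.
* `shared_variance_fraction = 0.65`, `paradigm_sd = 0.33`,
  `base_loading_sd = 0.15`: jointly calibrated so that the mean
  first-principal-component variance explained sits near 70%, the level
  reported for multi-paradigm clinical cohorts. The variance explained is
  monotone in the shared fraction, which the test suite asserts over a
  grid.
* `covariate_model` (FD 0.24, dose 0.24, age 0.10 Fisher-z per SD) and
  `trait_level_sd = 0.12`: motion, medication and age jointly carry most
  of the between-subject variance in apparent network strength. This is
  deliberately strong — it reflects why nuisance regression exists in this
  literature, and it is what covariate adjustment must be able to remove.
* `phenotype_coupling = 0.5`: symptom scores load positively, and
  months-to-conversion negatively, on the standardized planted-network
  strength, with unit residual noise.

### What the generator does not emulate

No haemodynamics, no autocorrelated BOLD noise, no voxel data, no scanner
or site artifacts beyond a categorical covariate, no missing phenotypes,
independent-per-run sampling noise, or negative-baseline planted circuits.
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under the stated assumptions, not that the pipeline
is robust to everything real data can do.

## Numerical choices and degenerate inputs

* Edge order is fixed package-wide: 0-based node ids, `i < j`, row-major
  upper triangle. `vectorize_edges()`/`devectorize_edges()` are exact
  inverses and validate symmetry.
* Rank-deficient nuisance matrices drop collinear columns with a warning;
  rank-deficient group designs abort naming the collinear columns.
* The edge-wise engine detects flat responses (F = 0, p = 1) and perfect
  separation (F = Inf, p = 0) by scale-aware thresholds rather than exact
  zero tests.
* Zero-phase Butterworth filtering (order 2, forward-backward) is used for
  the temporal filter; the contract is spectral (stop-band at least 20 dB
  down, pass band within 10%), which the tests verify on probe sinusoids.
  The series mean is removed exactly before any filter whose pass band
  excludes DC.
* Permutation p values use the +1 correction; all stochastic operations
  take explicit integer seeds, and results are invariant to subject row
  order (rows are sorted internally by subject id).
* Spearman p values are exact for n at most 10 without ties and use the t
  approximation otherwise.
* In `plant_network(connected = TRUE)` the planted truth is a compact
  near-clique module (smallest node cluster whose capacity is 1.2 times the
  edge count). Two reasons. First, component-based inference can only
  report connected edge sets, so a recoverable ground truth must be
  connected — a uniform 30-edge mask on 60 nodes has mean degree 1, the
  percolation threshold, and is almost surely fragmented. Second, under
  the mixing mechanism a *sparse* connected cluster leaks group signal
  onto uninvolved within-cluster pairs, which are then correctly detected
  and would be counted against recovery; a near-clique leaves few such
  pairs.

## Design decisions on open points

* The group contrast of the edge-wise test is the omnibus F over the
  ordered groups; an ordered linear-trend contrast is available in the
  post-hoc layer (`ancova_group_test(contrast = "linear_trend")`).
* The winning mask of an NBS run is the union of all components at
  `fwe_p <= alpha`, not only the largest: more than one true component can
  be significant.
* Specificity draws sample from *all* edges, including the observed
  network's own edges.
* Subset analyses (matched subsamples, minimum follow-up) are plain
  re-runs on filtered sample sheets; no special code path exists.
* Fisher-z transformation of edge values is available but off by default;
  all default analyses work on raw correlations.

## Problem sizes used by the checks

The simulation-based checks run at desk scale, chosen as the smallest
sizes at which the asymptotic properties are visible: null FWE calibration
uses 200 cohorts of 90 subjects (60 nodes, 3 paradigms, 100 timepoints)
with 500 permutations each; planted-network recovery uses 50 replicates of
80 subjects at the generator defaults; phenotype-coupling recovery uses 50
replicates of 100 subjects at 40 nodes and 2 paradigms. Each check states
its tolerance in the test itself, and none of the empirical numbers quoted
in this vignette (the extent-vs-intensity FWE contrast, the ~70% variance
explained) come from anywhere but those runs.

## Known limitations

* Parametric edge-wise p values are used only to set the primary
  threshold; their marginal miscalibration under non-normal edge
  distributions changes the effective sparsity of the suprathreshold graph
  but not the validity of the permutation FWE.
* The extent statistic's discreteness makes its FWE conservative at sparse
  thresholds (see above).
* The generator's strength response saturates at high mixing weights; the
  few subjects in the heavy upper tail of the strength distribution sit on
  a ceiling, and requested effects beyond the response range abort with an
  explanatory error rather than silently delivering less.
* At 270 nodes a cohort of 90 subjects with 5 paradigms holds roughly
  130 MB of time series; the pipeline runs, but permutation counts in the
  thousands are the practical limit on a laptop.
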