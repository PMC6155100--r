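# Configuration for the synthetic multi-paradigm cohort generator.

#' Configure a synthetic multi-paradigm cohort
#'
#' Builds a validated configuration for [generate_cohort()]. The generative
#' model produces, for every subject s and paradigm p, a valid correlation
#' matrix by construction:
#'
#' * a cohort-level base covariance from a low-rank factor model
#'   (`base_rank` factors, loadings `W0`, plus a diagonal);
#' * subject topography: loadings `W_s = W0 + sqrt(f) * w_a * Xi_s`;
#' * paradigm state: loadings `W_sp = W_s + sqrt(1 - f) * w_b * Xi_sp`,
#'   where `f` is `shared_variance_fraction` (at `f = 1` all paradigms of a
#'   subject share one covariance);
#' * planted-network strength as symmetric signal mixing between the mask
#'   node pairs: `Sigma' = M Sigma M` with `M = I + Theta`, a congruence
#'   transform that stays positive semi-definite for any mixing weight. The
#'   baseline weight puts the mask edges' mean Fisher-z value at
#'   `mask_base_z` (the circuit exists in everyone); the subject's weight
#'   adds `q_s = covariate_model %*% (age, fd, dose) + eta_s` and the
#'   group shift `Delta_g`, both converted from Fisher-z to mixing units by
#'   numerically inverting the (concave) strength response;
#' * a global connectivity modulation `c_s <= 1` (a convex blend of the
#'   correlation matrix with the identity), mildly driven by motion and age;
#' * node time series drawn from each scan's correlation structure with one
#'   innovation sequence per subject shared across paradigms, plus white
#'   measurement noise `noise_sd`.
#'
#' Group shifts are calibrated against the realized between-subject SD of
#' the across-paradigm mean planted-edge value (on the observed scale,
#' including the analytic measurement-noise attenuation), so the realized
#' Cohen's d of the mean planted-edge connectivity matches `effect_sizes`
#' up to finite-scan sampling noise.
#'
#' @param n_nodes Number of atlas nodes (default 60; the full 270-node atlas
#'   is supported but slow and memory-hungry for routine use).
#' @param n_paradigms Number of fMRI paradigms per subject.
#' @param group_sizes Named integer vector of subjects per ordered outcome
#'   group, lowest risk first.
#' @param timepoints Scans per paradigm: scalar or length-`n_paradigms`.
#' @param planted_edge_count Edges in the planted hyperconnected subnetwork
#'   (ignored when `planted_mask` is given).
#' @param planted_mask Optional [network_mask()] fixing the planted edges.
#' @param planted_connected If `TRUE` (and no `planted_mask`), plant a
#'   connected subnetwork via `plant_network(connected = TRUE)`.
#' @param effect_sizes Per-group standardized shift (Cohen's d units) of the
#'   mean planted-edge connectivity, one per group, monotone non-decreasing
#'   when `graded = TRUE`.
#' @param shared_variance_fraction Fraction `f` of the subject-and-paradigm
#'   deviation budget carried by the subject's latent trait (in \[0, 1\]).
#' @param noise_sd SD of white measurement noise added to each scan's time
#'   series (signal series have roughly unit variance).
#' @param covariate_model Named list of slopes per SD of covariate on the
#'   latent planted-network strength (Fisher-z units): `age`, `fd`, `dose`.
#' @param phenotype_coupling Slope linking the standardized planted-network
#'   strength to symptom scores (positive) and to months-to-conversion
#'   (negative).
#' @param dropout_prob Per-subject-paradigm probability of a missing scan
#'   (at least two paradigms are always retained).
#' @param trait_level_sd Residual (covariate-free) SD of the latent
#'   planted-network strength, Fisher-z units.
#' @param subject_topography_sd Loading-perturbation SD for subject
#'   topography (`w_a`).
#' @param paradigm_sd Loading-perturbation SD for paradigm state (`w_b`).
#' @param mask_base_z Mean baseline Fisher-z value of planted edges.
#' @param base_rank,base_loading_sd Rank and loading SD of the base factor
#'   model.
#' @param sampling_interval Repetition time of the simulated scans, seconds.
#' @param graded Enforce monotone non-decreasing `effect_sizes`.
#' @param seed Integer seed; the cohort is fully reproducible given the
#'   configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 60,
                         n_paradigms = 5,
                         group_sizes = c(control = 30, nonconverter = 30,
                                         converter = 30),
                         timepoints = 240,
                         planted_edge_count = 30,
                         planted_mask = NULL,
                         planted_connected = FALSE,
                         effect_sizes = c(0, 0.5, 1),
                         shared_variance_fraction = 0.65,
                         noise_sd = 0.2,
                         covariate_model = list(age = 0.10, fd = 0.24,
                                                dose = 0.24),
                         phenotype_coupling = 0.5,
                         dropout_prob = 0,
                         trait_level_sd = 0.12,
                         subject_topography_sd = 0.10,
                         paradigm_sd = 0.33,
                         mask_base_z = 0.40,
                         base_rank = 5,
                         base_loading_sd = 0.15,
                         sampling_interval = 2,
                         graded = TRUE,
                         seed = 1) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 4L)
  n_paradigms <- check_count(n_paradigms, "n_paradigms", min = 2L)
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("group", seq_along(group_sizes))
  }
  if (length(group_sizes) < 2L || any(group_sizes < 2)) {
    abort("group_sizes must give >= 2 groups with >= 2 subjects each")
  }
  group_sizes <- vapply(group_sizes, check_count, integer(1),
                        name = "group_sizes", min = 2L)
  if (length(timepoints) == 1L) {
    timepoints <- rep(timepoints, n_paradigms)
  }
  if (length(timepoints) != n_paradigms) {
    abort("timepoints must be scalar or one per paradigm")
  }
  timepoints <- vapply(timepoints, check_count, integer(1),
                       name = "timepoints", min = 16L)
  e_total <- n_edges_for(n_nodes)
  if (!is.null(planted_mask)) {
    planted_mask <- network_mask(planted_mask, n_nodes)
    planted_edge_count <- nrow(planted_mask)
  } else {
    planted_edge_count <- check_count(planted_edge_count,
                                      "planted_edge_count", min = 1L)
  }
  if (planted_edge_count > e_total) {
    abort(sprintf(
      "planted_edge_count (%d) exceeds n_nodes*(n_nodes-1)/2 = %d",
      planted_edge_count, e_total))
  }
  if (length(effect_sizes) != length(group_sizes)) {
    abort("effect_sizes must have one entry per group")
  }
  if (graded && is.unsorted(effect_sizes)) {
    abort("effect_sizes must be monotone non-decreasing over ordered groups")
  }
  shared_variance_fraction <- check_fraction(shared_variance_fraction,
                                             "shared_variance_fraction")
  dropout_prob <- check_fraction(dropout_prob, "dropout_prob")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  stopifnot(is.list(covariate_model))
  covariate_model <- modifyList(list(age = 0, fd = 0, dose = 0),
                                covariate_model)
  cfg <- list(
    n_nodes = n_nodes, n_paradigms = n_paradigms, group_sizes = group_sizes,
    timepoints = timepoints, planted_edge_count = planted_edge_count,
    planted_mask = planted_mask, planted_connected = planted_connected,
    effect_sizes = as.numeric(effect_sizes),
    shared_variance_fraction = shared_variance_fraction,
    noise_sd = as.numeric(noise_sd), covariate_model = covariate_model,
    phenotype_coupling = as.numeric(phenotype_coupling),
    dropout_prob = dropout_prob,
    trait_level_sd = as.numeric(trait_level_sd),
    subject_topography_sd = as.numeric(subject_topography_sd),
    paradigm_sd = as.numeric(paradigm_sd),
    mask_base_z = as.numeric(mask_base_z),
    base_rank = check_count(base_rank, "base_rank"),
    base_loading_sd = as.numeric(base_loading_sd),
    sampling_interval = as.numeric(sampling_interval),
    graded = isTRUE(graded), seed = check_count(seed, "seed", min = 0L))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d nodes, %d paradigms, groups: %s\n", x$n_nodes,
              x$n_paradigms,
              paste(names(x$group_sizes), x$group_sizes, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  planted edges: %d, effect sizes: %s\n",
              x$planted_edge_count,
              paste(x$effect_sizes, collapse = "/")))
  cat(sprintf("  shared variance fraction: %.2f, seed: %d\n",
              x$shared_variance_fraction, x$seed))
  invisible(x)
}
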