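# End-to-end orchestration: simulate -> connect -> pca -> nbs -> posthoc.

#' Validate a pipeline configuration
#'
#' @param config Named list (or YAML file path) with elements
#'   `synth` (arguments for [synth_config()]), `covariates`,
#'   `threshold_p`, `n_permutations`, `alpha`, `filter`, `regress`, `seed`.
#'   Missing elements take the defaults shown in [run_pipeline()].
#' @return The completed, validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(synth = list(), covariates = c("age", "sex", "iq", "site",
                                                  "fd", "dose"),
                   threshold_p = 0.001, n_permutations = 1000, alpha = 0.05,
                   filter = "none", regress = TRUE, seed = 1)
  cfg <- modifyList(defaults, config)
  if (!is.numeric(cfg$threshold_p) || cfg$threshold_p <= 0 ||
      cfg$threshold_p >= 1) {
    abort("config threshold_p must lie in (0, 1)")
  }
  cfg$n_permutations <- check_count(cfg$n_permutations, "n_permutations",
                                    min = 100L)
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  if (!cfg$filter %in% c("none", "rest", "task")) {
    abort("config filter must be one of none/rest/task")
  }
  cfg$synth$seed <- cfg$synth$seed %||% cfg$seed
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic analysis pipeline
#'
#' Generates a cohort, builds connectivity matrices, extracts the
#' cross-paradigm trait matrices, runs the NBS group test, and applies the
#' post-hoc battery (trend test, effect sizes, phenotype correlations,
#' paradigm-wise tests) to the winning network. A provenance record (config
#' hash, seed, package version) is attached to the result and, when
#' `out_dir` is given, all artifacts are written as plain-text files.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `xpconn_pipeline` with elements `cohort`, `trait`,
#'   `nbs`, `posthoc`, `provenance`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- pipeline_config(config)
  synth <- do.call(synth_config, cfg$synth)
  cohort <- generate_cohort(synth)
  tr <- cohort_trait_edges(cohort, regress = cfg$regress, filter = cfg$filter)
  nbs <- nbs_test(tr$trait, cohort$design, covariates = cfg$covariates,
                  threshold_p = cfg$threshold_p,
                  n_permutations = cfg$n_permutations,
                  seed = cfg$seed, alpha = cfg$alpha)
  mask <- if (nrow(nbs$winning_mask) > 0) nbs$winning_mask else NULL
  post <- if (!is.null(mask)) {
    pipeline_posthoc(cohort, tr, mask, cfg)
  } else {
    list(note = "no FWE-significant network; post-hoc battery skipped")
  }
  provenance <- list(config_hash = rlang::hash(cfg), seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("xpconn")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(list(config = cfg, cohort = cohort, trait = tr, nbs = nbs,
                        posthoc = post, provenance = provenance),
                   class = "xpconn_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    readr::write_tsv(tr$pca, file.path(out_dir, "pca_summary.tsv"))
    write_edge_list(nbs$winning_mask, file.path(out_dir, "winning_mask.tsv"))
    jsonlite::write_json(
      list(glance = glance(nbs), components = tidy(nbs),
           null_max = nbs$null_max, provenance = provenance),
      file.path(out_dir, "nbs.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(post$reports)) {
      readr::write_tsv(post$reports, file.path(out_dir, "posthoc.tsv"))
    }
  }
  out
}

pipeline_posthoc <- function(cohort, tr, mask, cfg) {
  design <- cohort$design
  scores <- network_mean(tr$trait, mask)
  dat <- design
  dat$network_mean <- scores[match(dat$subject_id, rownames(tr$trait))]
  dat <- left_join(dat, cohort$phenotypes, by = "subject_id")
  reports <- bind_rows(
    ancova_group_test(dat, "network_mean", cfg$covariates, "omnibus"),
    ancova_group_test(dat, "network_mean", cfg$covariates, "linear_trend"),
    pairwise_posthoc(dat, "network_mean", cfg$covariates),
    correlate_vars(dat$network_mean, dat$symptom_disorganization,
                   method = "spearman"),
    {
      conv <- dat[!is.na(dat$months_to_conversion), ]
      if (nrow(conv) >= 4) {
        correlate_vars(conv$network_mean, conv$months_to_conversion,
                       method = "spearman")
      } else {
        NULL
      }
    })
  # per-paradigm means from the original connectivity matrices
  idx <- cohort$scan_index
  pm <- idx
  pm$value <- network_mean(tr$connectivity[idx$scan, , drop = FALSE], mask)
  paradigm_tests <- paradigm_wise_group_tests(pm, design, cfg$covariates)
  lv <- levels(design$group)
  d_top <- cohens_d(scores[design$group == lv[length(lv)]],
                    scores[design$group == lv[1L]])
  list(reports = reports, paradigm_tests = paradigm_tests,
       network_mean = dat[, c("subject_id", "group", "network_mean")],
       cohens_d_extremes = d_top)
}

#' @export
print.xpconn_pipeline <- function(x, ...) {
  cat("<xpconn_pipeline>\n")
  print(x$nbs)
  if (!is.null(x$posthoc$reports)) {
    cat("post-hoc reports:\n")
    print(x$posthoc$reports[, c("test", "statistic", "value", "p")])
  }
  invisible(x)
}
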