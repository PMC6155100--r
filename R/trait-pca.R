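# Per-subject PCA across paradigm connectivity matrices: the
# "cross-paradigm connectivity" trait.
#
# Orientation: edges are observations, paradigms are variables, so the fit
# yields one loading per paradigm and one first-PC score per edge.

#' Cross-paradigm PCA for one subject
#'
#' Fits a covariance PCA over a subject's paradigm-wise edge vectors:
#' columns (paradigms) are mean-centered but not scaled, components come
#' from the eigendecomposition of the paradigm-by-paradigm covariance, and
#' the first-PC edge scores are the centered data projected on the first
#' loading vector. The component sign is fixed so that the scores correlate
#' non-negatively with the across-paradigm mean edge value: a higher score
#' means stronger shared connectivity.
#'
#' @param edge_vectors Edge-by-paradigm numeric matrix (one column per
#'   available paradigm; at least 2), or a list of edge vectors.
#' @param standardize Scale columns to unit variance before the fit
#'   (default `FALSE`, keeping paradigm amplitude differences meaningful).
#' @return An object of class `cp_pca`: `scores` (first-PC score per edge),
#'   `loadings` (unit-norm, one per paradigm, first component),
#'   `variance_explained` (all components, sums to 1), `rotation` (full
#'   loading matrix), `n_paradigms`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' fit <- fit_cross_paradigm_pca(x)
#' glance(fit)
fit_cross_paradigm_pca <- function(edge_vectors, standardize = FALSE) {
  if (is.list(edge_vectors)) {
    edge_vectors <- do.call(cbind, edge_vectors)
  }
  x <- as.matrix(edge_vectors)
  if (ncol(x) < 2L) abort("need >= 2 paradigms for a cross-paradigm PCA")
  if (any(!is.finite(x))) abort("edge vectors contain non-finite values")
  k <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("paradigm", seq_len(k))
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  total_var <- sum(fit$sdev^2)
  if (total_var <= .Machine$double.eps) {
    abort("zero total variance across paradigms; PCA is undefined")
  }
  ve <- fit$sdev^2 / total_var
  scores <- fit$x[, 1L]
  loadings <- fit$rotation[, 1L]
  # sign convention: scores track the across-paradigm mean edge value
  orient <- sum(scores * (rowMeans(x) - mean(rowMeans(x))))
  if (orient < 0) {
    scores <- -scores
    loadings <- -loadings
    fit$rotation[, 1L] <- loadings
  }
  structure(list(scores = as.numeric(scores),
                 loadings = as.numeric(loadings),
                 variance_explained = as.numeric(ve),
                 rotation = fit$rotation,
                 paradigms = colnames(x),
                 n_paradigms = k),
            class = "cp_pca")
}

#' @export
print.cp_pca <- function(x, ...) {
  cat(sprintf("<cp_pca> %d paradigms, %d edges; PC1 explains %.1f%% of variance\n",
              x$n_paradigms, length(x$scores), 100 * x$variance_explained[1L]))
  invisible(x)
}

#' @export
tidy.cp_pca <- function(x, ...) {
  tibble(paradigm = x$paradigms,
         loading = x$loadings)
}

#' @export
glance.cp_pca <- function(x, ...) {
  tibble(variance_explained_1 = x$variance_explained[1L],
         n_paradigms = x$n_paradigms,
         n_edges = length(x$scores))
}

#' Trait matrices for a whole cohort
#'
#' Runs the connectivity chain and the per-subject cross-paradigm PCA over
#' every subject of a cohort. Subjects with fewer than two available
#' paradigms are dropped with a warning.
#'
#' @inheritParams cohort_connectivity
#' @param standardize Passed to [fit_cross_paradigm_pca()].
#' @return A list with
#'   `trait` (subject-by-edge matrix of first-PC scores, rows named by
#'   subject), `pca` (tibble: subject_id, variance_explained_1,
#'   n_paradigms, and one `loading_<paradigm>` column per paradigm), and
#'   `connectivity` (the scan-by-edge matrix from [cohort_connectivity()]).
#' @export
cohort_trait_edges <- function(cohort, regress = TRUE,
                               filter = c("none", "rest", "task"),
                               fisher_z = FALSE, standardize = FALSE) {
  conn <- cohort_connectivity(cohort, regress = regress, filter = filter,
                              fisher_z = fisher_z)
  index <- conn$scan_index
  subjects <- unique(index$subject_id)
  paradigms <- sort(unique(index$paradigm))
  trait <- matrix(NA_real_, length(subjects), ncol(conn$edges),
                  dimnames = list(subjects, NULL))
  rows <- vector("list", length(subjects))
  keep <- logical(length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    idx <- index[index$subject_id == s, ]
    if (nrow(idx) < 2L) next
    x <- t(conn$edges[idx$scan, , drop = FALSE])
    colnames(x) <- idx$paradigm
    fit <- fit_cross_paradigm_pca(x, standardize = standardize)
    trait[si, ] <- fit$scores
    loading <- setNames(rep(NA_real_, length(paradigms)),
                        paste0("loading_", paradigms))
    loading[paste0("loading_", idx$paradigm)] <- fit$loadings
    rows[[si]] <- tibble(subject_id = s,
                         variance_explained_1 = fit$variance_explained[1L],
                         n_paradigms = fit$n_paradigms, !!!as.list(loading))
    keep[si] <- TRUE
  }
  if (!all(keep)) {
    warn(sprintf("dropping %d subject(s) with < 2 paradigms", sum(!keep)))
  }
  list(trait = trait[keep, , drop = FALSE],
       pca = bind_rows(rows[keep]),
       connectivity = conn$edges)
}

#' Group comparison of PCA summaries
#'
#' One-way ANOVA (optionally covariate-adjusted ANCOVA) of the first-PC
#' variance explained and of each paradigm's loading between groups.
#'
#' @param pca The `pca` tibble from [cohort_trait_edges()].
#' @param design Sample sheet with `subject_id` and `group`.
#' @param covariates Character vector of design columns to adjust for
#'   (default none: plain one-way ANOVA).
#' @return A tibble with one [stat_report] row per measure.
#' @export
summarize_pca_by_group <- function(pca, design, covariates = character(0)) {
  check_columns(pca, c("subject_id", "variance_explained_1"), "pca table")
  check_columns(design, c("subject_id", "group"), "design")
  data <- left_join(pca, design, by = "subject_id")
  counts <- table(data$group)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("need >= 2 groups with >= 2 subjects each")
  }
  measures <- c("variance_explained_1", grep("^loading_", names(pca),
                                             value = TRUE))
  bind_rows(lapply(measures, function(m) {
    res <- ancova_group_test(data, y = m, covariates = covariates)
    res$test <- paste0("group_anova:", m)
    res
  }))
}
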