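# Downstream statistics applied to a discovered network mask: network means,
# group/trend tests, effect sizes, phenotype correlations, random-edge
# specificity permutation, and ROC transfer.

#' Mean value over a network mask
#'
#' Arithmetic mean of the masked edges, per subject (matrix input, one row
#' per subject) or for a single connectivity matrix.
#'
#' @param values Subject-by-edge matrix, a single edge vector, or a
#'   node-by-node `connectivity_matrix`.
#' @param mask A [network_mask()].
#' @return Numeric scalar, or one value per row for matrix input.
#' @export
network_mean <- function(values, mask) {
  if (nrow(mask) == 0L) abort("mask is empty")
  if (inherits(values, "connectivity_matrix") ||
      (is.matrix(values) && nrow(values) == ncol(values) &&
       isTRUE(all.equal(unclass(values), t(unclass(values)))) &&
       all(abs(diag(values) - 1) < 1e-8))) {
    m <- unclass(values)
    return(mean(m[cbind(mask$node_i + 1L, mask$node_j + 1L)]))
  }
  if (is.matrix(values)) {
    ids <- mask_edge_ids(mask, nodes_for_edges(ncol(values)))
    return(rowMeans(values[, ids, drop = FALSE]))
  }
  ids <- mask_edge_ids(mask, nodes_for_edges(length(values)))
  mean(values[ids])
}

#' Covariate-adjusted group test on a per-subject scalar
#'
#' Omnibus: F test of the group factor after covariates (ANCOVA; one-way
#' ANOVA when `covariates` is empty). Linear trend: t test of an
#' ordered-group linear contrast after covariates.
#'
#' @param data Data frame with the response, `group`, and covariates.
#' @param y Name of the response column.
#' @param covariates Character vector of covariate columns.
#' @param contrast `"omnibus"` or `"linear_trend"`.
#' @param group_col Name of the group column (ordered factor or factor whose
#'   level order encodes the risk gradient).
#' @return A one-row [stat_report] tibble.
#' @export
ancova_group_test <- function(data, y, covariates = character(0),
                              contrast = c("omnibus", "linear_trend"),
                              group_col = "group") {
  contrast <- match.arg(contrast)
  check_columns(data, c(y, group_col, covariates), "data")
  dm <- build_designs(data, covariates, group_col = group_col)
  yy <- as.numeric(data[[y]])
  if (any(!is.finite(yy))) abort(sprintf("`%s` contains non-finite values", y))
  n <- length(yy)
  if (contrast == "omnibus") {
    bases <- design_bases(dm)
    res <- ancova_f_multi(matrix(yy, ncol = 1), bases)
    return(stat_report(test = paste0("ancova_omnibus:", y),
                       statistic = "F", value = res$f, p = res$p, n = n,
                       groups = paste(levels(dm$group), collapse = "/"),
                       df1 = bases$q, df2 = bases$df2))
  }
  # linear trend: equally spaced contrast scores over the ordered groups
  k <- nlevels(dm$group)
  scores <- stats::contr.poly(k)[, 1L]
  trend <- scores[as.integer(dm$group)]
  x <- cbind(dm$z, trend = trend)
  fit <- stats::lm.fit(x, yy)
  df2 <- n - ncol(x)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(rss / df2 * xtx_inv[ncol(x), ncol(x)])
  est <- unname(fit$coefficients["trend"])
  tval <- if (se == 0) {
    if (abs(est) < 1e-12) 0 else Inf * sign(est)
  } else {
    est / se
  }
  p <- if (is.infinite(tval)) 0 else 2 * pt(abs(tval), df2, lower.tail = FALSE)
  stat_report(test = paste0("ancova_linear_trend:", y),
              statistic = "t", value = unname(tval), p = unname(p), n = n,
              groups = paste(levels(dm$group), collapse = "/"),
              df1 = 1, df2 = df2,
              estimate = unname(fit$coefficients["trend"]))
}

#' Per-paradigm group tests with Bonferroni FWE
#'
#' Runs [ancova_group_test()] on the network-mean connectivity of each
#' paradigm and Bonferroni-corrects over the number of paradigms.
#'
#' @param paradigm_means Data frame with `subject_id`, `paradigm`, `value`.
#' @param design Sample sheet (joined by `subject_id`).
#' @inheritParams ancova_group_test
#' @return A [stat_report] tibble, one row per paradigm, with `p_adjusted`.
#' @export
paradigm_wise_group_tests <- function(paradigm_means, design,
                                      covariates = character(0),
                                      contrast = "omnibus") {
  check_columns(paradigm_means, c("subject_id", "paradigm", "value"),
                "paradigm_means")
  paradigms <- sort(unique(paradigm_means$paradigm))
  k <- length(paradigms)
  out <- bind_rows(lapply(paradigms, function(p) {
    dat <- left_join(paradigm_means[paradigm_means$paradigm == p, ],
                     design, by = "subject_id")
    res <- ancova_group_test(dat, "value", covariates, contrast = contrast)
    res$test <- paste0("paradigm:", p)
    res
  }))
  out$correction <- "bonferroni"
  out$p_adjusted <- pmin(1, k * out$p)
  out
}

#' Correlation with a tidy report
#'
#' Spearman rank-order (average ranks for ties; exact p for n <= 10 without
#' ties, t approximation otherwise) or Pearson correlation, two-sided, with
#' optional Bonferroni correction over a family of `fwe_n` tests.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @param method `"spearman"` or `"pearson"`.
#' @param fwe_n Family size for Bonferroni correction (default 1 = none).
#' @return A one-row [stat_report] tibble.
#' @export
correlate_vars <- function(x, y, method = c("spearman", "pearson"),
                           fwe_n = 1) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort("need >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  exact <- if (method == "spearman") {
    n <= 10L && !anyDuplicated(x) && !anyDuplicated(y)
  } else {
    NULL
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = method, exact = exact, alternative = "two.sided"))
  stat_report(test = paste0("correlation_", method),
              statistic = if (method == "spearman") "rho" else "r",
              value = unname(ct$estimate), p = ct$p.value, n = n,
              correction = if (fwe_n > 1) "bonferroni" else NA_character_,
              p_adjusted = if (fwe_n > 1) min(1, fwe_n * ct$p.value) else NA_real_)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled SD using the `n1 + n2 - 2` denominator.
#'
#' @param a,b Numeric vectors.
#' @return A single number.
#' @export
#' @examples
#' cohens_d(c(0, 2), c(1, 3))
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) abort("need >= 2 values per group")
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  (mean(a) - mean(b)) / sp
}

#' Random-edge specificity permutation test
#'
#' Compares the group effect on the observed network's mean against the
#' group effect on means of random edge sets of the same size drawn
#' uniformly from all edges (the observed network is not excluded). Reports
#' the observed omnibus ANCOVA p, the observed rank among the draws, and
#' whether the observed network (and any draw) survives Bonferroni
#' correction over the number of draws.
#'
#' @inheritParams edgewise_glm
#' @param mask Observed [network_mask()].
#' @param n_draws Number of random edge sets.
#' @param seed Integer seed.
#' @return List with `report` (a [stat_report] row: observed p, rank), the
#'   draw p values `null_p`, and flags `observed_survives_bonferroni`,
#'   `any_draw_survives_bonferroni`.
#' @export
edge_specificity_test <- function(trait_edges, design, mask,
                                  covariates = character(0),
                                  n_draws = 1000, seed = 1) {
  n_draws <- check_count(n_draws, "n_draws", min = 10L)
  al <- align_design(trait_edges, design)
  e_total <- ncol(al$y)
  n_nodes <- nodes_for_edges(e_total)
  ids <- mask_edge_ids(mask, n_nodes)
  m <- length(ids)
  if (m > e_total) abort("mask is larger than the edge set")
  dm <- build_designs(al$design, covariates)
  bases <- design_bases(dm)
  obs_mean <- rowMeans(al$y[, ids, drop = FALSE])
  obs_p <- ancova_f_multi(matrix(obs_mean, ncol = 1), bases)$p
  draw_means <- with_rng(seed, {
    vapply(seq_len(n_draws), function(i) {
      rowMeans(al$y[, sample.int(e_total, m), drop = FALSE])
    }, numeric(nrow(al$y)))
  })
  null_p <- ancova_f_multi(draw_means, bases)$p
  rank_obs <- 1L + sum(null_p < obs_p)
  report <- stat_report(test = "edge_specificity",
                        statistic = "ancova_p", value = obs_p,
                        p = rank_obs / (n_draws + 1), n = nrow(al$y),
                        correction = "bonferroni_over_draws",
                        seed = as.integer(seed),
                        rank = rank_obs, n_draws = n_draws)
  list(report = report, null_p = null_p,
       observed_p = obs_p, rank = rank_obs,
       observed_survives_bonferroni = obs_p <= 0.05 / n_draws,
       any_draw_survives_bonferroni = any(null_p <= 0.05 / n_draws))
}

#' ROC transfer test with a permutation null
#'
#' Rank-based AUC (ties contribute 1/2) for distinguishing cases from
#' controls by a network score, with a one-sided permutation p value
#' (label shuffles; AUC >= observed; +1 corrected).
#'
#' @param scores Numeric network score per subject.
#' @param labels Logical or two-level factor; `TRUE` (or the second level)
#'   marks cases.
#' @param n_permutations Number of label shuffles.
#' @param seed Integer seed.
#' @return List of class `roc_result`: `auc`, `p`, `null_auc`, plus the
#'   inputs for plotting.
#' @export
roc_transfer <- function(scores, labels, n_permutations = 1000, seed = 1) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- factor(labels)
    if (nlevels(labels) != 2L) abort("labels must have exactly two levels")
    labels <- labels == levels(labels)[2L]
  }
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)           # average ranks: ties count 1/2
  auc_from <- function(lab) {
    (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_from(labels)
  null_auc <- with_rng(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(length(r), n1)
      (sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }, numeric(1))
  })
  p <- (1 + sum(null_auc >= auc)) / (1 + n_permutations)
  structure(list(auc = auc, p = p, null_auc = null_auc,
                 scores = scores, labels = labels,
                 n_case = n1, n_control = n0,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (cases %d vs controls %d), permutation p = %.4g (%d shuffles)\n",
              x$auc, x$n_case, x$n_control, x$p, x$n_permutations))
  invisible(x)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, p = x$p, n_case = x$n_case, n_control = x$n_control,
         n_permutations = x$n_permutations)
}

#' Covariate-adjusted pairwise group contrasts
#'
#' Pairwise t tests between group levels within the full ANCOVA model
#' (shared covariate adjustment), Bonferroni-corrected over the number of
#' pairs.
#'
#' @inheritParams ancova_group_test
#' @return A [stat_report] tibble, one row per pair.
#' @export
pairwise_posthoc <- function(data, y, covariates = character(0),
                             group_col = "group",
                             correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  check_columns(data, c(y, group_col, covariates), "data")
  dm <- build_designs(data, covariates, group_col = group_col)
  yy <- as.numeric(data[[y]])
  x <- dm$x
  fit <- stats::lm.fit(x, yy)
  df2 <- length(yy) - ncol(x)
  sigma2 <- sum(fit$residuals^2) / df2
  xtx_inv <- chol2inv(chol(crossprod(x)))
  lv <- levels(dm$group)
  k <- length(lv)
  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)
  # group-level coefficient contrast vectors (reference level = 0)
  coef_of <- function(g) {
    v <- numeric(ncol(x))
    if (g > 1L) v[ncol(dm$z) + g - 1L] <- 1
    v
  }
  rows <- lapply(seq_len(n_pairs), function(ip) {
    g1 <- pairs[1L, ip]; g2 <- pairs[2L, ip]
    cvec <- coef_of(g2) - coef_of(g1)
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(sigma2 * drop(t(cvec) %*% xtx_inv %*% cvec))
    tval <- if (se == 0) {
      if (abs(est) < 1e-12) 0 else Inf * sign(est)
    } else {
      est / se
    }
    p <- if (is.infinite(tval)) 0 else 2 * pt(abs(tval), df2, lower.tail = FALSE)
    stat_report(test = sprintf("pairwise:%s-%s", lv[g2], lv[g1]),
                statistic = "t", value = tval, p = p, n = length(yy),
                correction = correction,
                p_adjusted = if (correction == "bonferroni") {
                  min(1, n_pairs * p)
                } else p,
                groups = sprintf("%s/%s", lv[g2], lv[g1]),
                estimate = est, df2 = df2)
  })
  bind_rows(rows)
}
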