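# Network-based statistic: edge-wise covariate-adjusted group GLM,
# suprathreshold component search, and max-component permutation FWE with
# the Freedman-Lane scheme (reduced-model residuals are permuted, so the
# null respects the nuisance covariates).

# --- design matrices ------------------------------------------------------

# Reduced (intercept + covariates) and full (+ group dummies) design
# matrices. Categorical columns are dummy-coded dropping the first level.
build_designs <- function(design, covariates, group_col = "group") {
  check_columns(design, c(group_col, covariates), "design")
  g <- design[[group_col]]
  if (!is.factor(g)) g <- factor(g)
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("need >= 2 groups with >= 2 subjects each")
  }
  n <- nrow(design)
  cols <- list("(Intercept)" = rep(1, n))
  for (cv in covariates) {
    v <- design[[cv]]
    if (is.numeric(v)) {
      cols[[cv]] <- v
    } else {
      f <- factor(v)
      if (nlevels(f) > 1L) {
        mm <- model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1L])
        cols[[cv]] <- mm
      }
    }
  }
  z <- do.call(cbind, cols)
  colnames(z)[1L] <- "(Intercept)"
  # treatment dummies regardless of factor orderedness (ordered factors
  # would otherwise get polynomial contrasts, breaking pairwise contrasts)
  g_plain <- factor(as.character(g), levels = levels(g))
  gd <- model.matrix(~g_plain)[, -1L, drop = FALSE]
  colnames(gd) <- paste0(group_col, levels(g)[-1L])
  x <- cbind(z, gd)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  list(z = z, gd = gd, x = x, group = g, q = ncol(gd))
}

# Orthonormal bases: qz spans the reduced model, qg its orthogonal
# complement within the full model (so [qz qg] spans the full model).
design_bases <- function(dm) {
  qz <- qr.Q(qr(dm$z))
  g_res <- dm$gd - qz %*% crossprod(qz, dm$gd)
  qg <- qr.Q(qr(g_res))
  list(qz = qz, qg = qg, q = dm$q,
       df2 = nrow(dm$x) - ncol(dm$x))
}

# Vectorized extra-sum-of-squares F tests of the group factor for a
# multi-column response after covariate adjustment.
ancova_f_multi <- function(y, bases) {
  y <- as.matrix(y)
  e0 <- y - bases$qz %*% crossprod(bases$qz, y)   # reduced-model residuals
  ss0 <- colSums(e0^2)
  c1 <- colSums(crossprod(bases$qg, e0)^2)
  rss1 <- pmax(ss0 - c1, 0)
  # scale-aware zero detection: a response flat after covariate adjustment
  # has no group effect; a response perfectly explained by the group factor
  # has an infinite F
  scale_ref <- colSums(y^2) + 1e-300
  flat <- ss0 <= 1e-16 * scale_ref
  exact <- !flat & rss1 <= 1e-12 * ss0
  f <- (c1 / bases$q) / (rss1 / bases$df2)
  f[flat] <- 0
  f[exact] <- Inf
  p <- pf(f, bases$q, bases$df2, lower.tail = FALSE)
  p[flat] <- 1
  p[exact] <- 0
  list(f = as.numeric(f), p = as.numeric(p), e0 = e0, ss0 = ss0)
}

# --- edge-wise GLM --------------------------------------------------------

#' Edge-wise covariate-adjusted group test
#'
#' For every edge, an extra-sum-of-squares F test of the group factor after
#' covariate adjustment (reduced model: intercept + covariates; full model:
#' + group dummies), with the parametric p value.
#'
#' @param trait_edges Subject-by-edge matrix (rows named by subject id align
#'   the design; otherwise row order is assumed to match).
#' @param design Sample sheet with a `group` column and the covariates.
#' @param covariates Character vector of design columns to adjust for.
#' @return Tibble with `edge`, `node_i`, `node_j`, `statistic` (F), `p`;
#'   degrees of freedom in attribute `df`.
#' @export
edgewise_glm <- function(trait_edges, design, covariates = character(0)) {
  al <- align_design(trait_edges, design)
  dm <- build_designs(al$design, covariates)
  bases <- design_bases(dm)
  res <- ancova_f_multi(al$y, bases)
  n_nodes <- nodes_for_edges(ncol(al$y))
  out <- edge_table(n_nodes)
  out$statistic <- res$f
  out$p <- res$p
  attr(out, "df") <- c(df1 = bases$q, df2 = bases$df2)
  out
}

align_design <- function(trait_edges, design) {
  y <- as.matrix(trait_edges)
  check_columns(design, "subject_id", "design")
  if (!is.null(rownames(y))) {
    if (!setequal(rownames(y), design$subject_id)) {
      abort("trait row names and design subject_id do not match")
    }
    # canonical subject order makes results invariant to input row order
    ord <- order(rownames(y))
    y <- y[ord, , drop = FALSE]
    design <- design[match(rownames(y), design$subject_id), , drop = FALSE]
  } else if (nrow(y) != nrow(design)) {
    abort("trait matrix and design have different numbers of subjects")
  }
  list(y = y, design = design)
}

nodes_for_edges <- function(e) {
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (n != floor(n)) abort("edge count is not n(n-1)/2 for integer n")
  as.integer(n)
}

# --- components -----------------------------------------------------------

# Union-find with path halving; edges is an integer matrix of 0-based pairs.
# Returns a component id per edge (components connected via shared nodes).
edge_components <- function(edges_i, edges_j) {
  m <- length(edges_i)
  if (m == 0L) return(integer(0))
  parent <- seq_len(max(edges_j) + 1L)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_len(m)) {
    ra <- find(edges_i[e] + 1L)
    rb <- find(edges_j[e] + 1L)
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(edges_i + 1L, find, integer(1))
  match(roots, unique(roots))
}

#' Connected components of suprathreshold edges
#'
#' Thresholds edge statistics and partitions the surviving edges into
#' components connected via shared nodes.
#'
#' @param edge_stats Output of [edgewise_glm()] (or any tibble with `edge`,
#'   `node_i`, `node_j`, `statistic`, `p`).
#' @param threshold_p Primary threshold as an edge-wise p-value cutoff.
#' @param threshold_f Alternatively, an F cutoff (used if not `NULL`).
#' @return Tibble of suprathreshold edges with a `component` id and the
#'   component `size` (edge count); empty tibble when nothing survives.
#' @export
threshold_components <- function(edge_stats, threshold_p = 0.001,
                                 threshold_f = NULL) {
  check_columns(edge_stats, c("edge", "node_i", "node_j", "statistic", "p"),
                "edge_stats")
  keep <- if (!is.null(threshold_f)) {
    edge_stats$statistic > threshold_f
  } else {
    edge_stats$p < threshold_p
  }
  sub <- edge_stats[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble(edge = integer(0), node_i = integer(0),
                  node_j = integer(0), statistic = numeric(0),
                  p = numeric(0), component = integer(0), size = integer(0)))
  }
  comp <- edge_components(sub$node_i, sub$node_j)
  sizes <- tabulate(comp)
  # relabel by decreasing size for stable reporting
  relabel <- order(order(-sizes, seq_along(sizes)))
  sub$component <- relabel[comp]
  sub$size <- sizes[comp]
  arrange(sub, .data$component, .data$edge)
}

# --- NBS permutation test -------------------------------------------------

#' Network-based statistic with permutation FWE
#'
#' Edge-wise covariate-adjusted F tests, suprathreshold component formation,
#' and family-wise-error-corrected component p values from the permutation
#' distribution of the maximal component statistic. Permutation uses the
#' Freedman-Lane scheme: residuals of the reduced (covariate-only) model are
#' row-permuted, the full model is refitted, and the identical threshold and
#' component procedure is applied.
#'
#' @inheritParams edgewise_glm
#' @param threshold_p Primary edge-wise p-value threshold (the conventional
#'   default 0.001; no canonical value exists, so sweep it when in doubt).
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param statistic Component statistic: `"extent"` (edge count) or
#'   `"intensity"` (sum of F minus the critical F over the component).
#' @param alpha FWE level used to assemble the winning mask.
#' @return Object of class `nbs_result`; see [tidy.nbs_result()] and
#'   [glance.nbs_result()].
#' @export
nbs_test <- function(trait_edges, design, covariates = character(0),
                     threshold_p = 0.001, n_permutations = 1000, seed = 1,
                     statistic = c("extent", "intensity"), alpha = 0.05) {
  statistic <- match.arg(statistic)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
  if (!is.numeric(threshold_p) || threshold_p <= 0 || threshold_p >= 1) {
    abort("threshold_p must lie in (0, 1)")
  }
  al <- align_design(trait_edges, design)
  dm <- build_designs(al$design, covariates)
  bases <- design_bases(dm)
  n <- nrow(al$y)
  e_total <- ncol(al$y)
  n_nodes <- nodes_for_edges(e_total)
  f_crit <- qf(1 - threshold_p, bases$q, bases$df2)

  obs <- ancova_f_multi(al$y, bases)
  stats_tbl <- edge_table(n_nodes)
  stats_tbl$statistic <- obs$f
  stats_tbl$p <- obs$p
  comps <- threshold_components(stats_tbl, threshold_f = f_crit)
  comp_stat <- function(f_vals, comp_ids) {
    if (length(f_vals) == 0L) return(numeric(0))
    if (statistic == "extent") {
      as.numeric(tabulate(comp_ids))
    } else {
      as.numeric(rowsum(f_vals - f_crit, comp_ids))
    }
  }
  obs_stats <- comp_stat(comps$statistic, comps$component)

  ## permutation null of the max component statistic
  qall <- rbind(t(bases$qz), t(bases$qg))
  pz <- ncol(bases$qz)
  p_all <- nrow(qall)
  e0 <- obs$e0
  ss0 <- obs$ss0
  idx_tbl <- edge_table(n_nodes)
  null_max <- numeric(n_permutations)
  chunk <- max(1L, min(250L, floor(2e7 / e_total)))
  with_rng(seed, {
    done <- 0L
    while (done < n_permutations) {
      b <- min(chunk, n_permutations - done)
      perms <- replicate(b, sample.int(n), simplify = FALSE)
      big <- do.call(rbind, lapply(perms, function(pp) qall[, pp]))
      m2 <- (big %*% e0)^2
      dim(m2) <- c(p_all, b, e_total)
      c0 <- colSums(m2[seq_len(pz), , , drop = FALSE])     # b x E
      ctot <- colSums(m2)
      c1 <- ctot - c0
      rss1 <- sweep(-(c0 + c1), 2L, ss0, `+`)
      rss1[rss1 < 0] <- 0
      fmat <- (c1 / bases$q) / (rss1 / bases$df2)
      fmat[rss1 <= 0] <- Inf
      for (bb in seq_len(b)) {
        sup <- which(fmat[bb, ] > f_crit)
        null_max[done + bb] <- if (length(sup) == 0L) 0 else {
          cid <- edge_components(idx_tbl$node_i[sup], idx_tbl$node_j[sup])
          max(comp_stat(fmat[bb, sup], cid))
        }
      }
      done <- done + b
    }
  })

  fwe_p <- vapply(obs_stats, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_permutations)
  }, numeric(1))
  comp_tbl <- if (length(obs_stats) > 0) {
    tibble(component = seq_along(obs_stats),
           size = as.integer(tabulate(comps$component)),
           statistic = obs_stats, fwe_p = fwe_p)
  } else {
    tibble(component = integer(0), size = integer(0),
           statistic = numeric(0), fwe_p = numeric(0))
  }
  winning <- comps[comps$component %in%
                     comp_tbl$component[comp_tbl$fwe_p <= alpha], ,
                   drop = FALSE]
  winning_mask <- if (nrow(winning) > 0) {
    network_mask(winning[, c("node_i", "node_j")], n_nodes)
  } else {
    network_mask(tibble(node_i = integer(0), node_j = integer(0)), n_nodes)
  }
  structure(list(edge_stats = stats_tbl,
                 primary_threshold = c(p = threshold_p, f = f_crit),
                 components = comp_tbl,
                 component_edges = comps,
                 observed_max = if (length(obs_stats)) max(obs_stats) else 0,
                 null_max = null_max,
                 winning_mask = winning_mask,
                 statistic = statistic, alpha = alpha,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 df = c(df1 = bases$q, df2 = bases$df2),
                 n_nodes = n_nodes, n_subjects = n),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d subjects, %d nodes, primary p < %g (F > %.2f), %d permutations\n",
              x$n_subjects, x$n_nodes, x$primary_threshold["p"],
              x$primary_threshold["f"], x$n_permutations))
  if (nrow(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    print(x$components)
    cat(sprintf("  winning mask: %d edge(s) at FWE alpha %.2f\n",
                nrow(x$winning_mask), x$alpha))
  }
  invisible(x)
}

#' Tidy an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return One row per observed component: size, statistic, FWE p.
#' @export
tidy.nbs_result <- function(x, ...) x$components

#' One-line summary of an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble(n_components = nrow(x$components),
         observed_max = x$observed_max,
         min_fwe_p = if (nrow(x$components)) min(x$components$fwe_p) else NA_real_,
         winning_edges = nrow(x$winning_mask),
         n_permutations = x$n_permutations,
         threshold_p = unname(x$primary_threshold["p"]),
         statistic = x$statistic,
         n_subjects = x$n_subjects)
}
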