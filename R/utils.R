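# Shared helpers: canonical edge indexing, seeded RNG, input checks.
#
# Edge convention (used by every module): undirected edges (i, j) with
# 0-based node ids and i < j, enumerated in row-major upper-triangle order:
# (0,1), (0,2), ..., (0,n-1), (1,2), ... This is the single source of truth
# for mapping between matrices, edge vectors, and edge lists.

#' Number of edges for a given node count
#'
#' @param n_nodes Number of nodes.
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @export
#' @examples
#' n_edges_for(270)
n_edges_for <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), n_nodes >= 1)
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Canonical edge table for a node count
#'
#' Enumerates all undirected edges over `n_nodes` nodes in the package's
#' canonical order (0-based ids, i < j, row-major upper triangle).
#'
#' @param n_nodes Number of nodes.
#' @return A tibble with columns `edge` (1-based position), `node_i`,
#'   `node_j` (0-based ids).
#' @export
edge_table <- function(n_nodes) {
  idx <- edge_index(n_nodes)
  tibble(edge = seq_len(nrow(idx)),
         node_i = idx[, 1L], node_j = idx[, 2L])
}

# Integer matrix of 0-based (i, j) pairs in canonical order.
edge_index <- function(n_nodes) {
  n <- as.integer(n_nodes)
  i <- rep.int(0:(n - 2L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

# Canonical 1-based edge position of 0-based pairs (i < j).
edge_position <- function(i, j, n_nodes) {
  if (any(i >= j)) abort("edge pairs must satisfy node_i < node_j")
  if (any(i < 0) || any(j >= n_nodes)) {
    abort(sprintf("edge node ids must lie in [0, %d]", n_nodes - 1L))
  }
  as.integer(i * n_nodes - i * (i + 1) / 2 + (j - i))
}

# Evaluate `expr` under a locally-seeded RNG without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# One-row stat report used by the post-hoc battery.
stat_report <- function(test, statistic, value, p, n,
                        correction = NA_character_, p_adjusted = NA_real_,
                        groups = NA_character_, seed = NA_integer_, ...) {
  tibble(test = test, statistic = statistic, value = value, p = p, n = n,
         correction = correction, p_adjusted = p_adjusted,
         groups = groups, seed = seed, ...)
}
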