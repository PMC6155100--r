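# Network masks: sets of undirected edges over the atlas nodes.

#' Construct a network mask from an edge table
#'
#' A network mask is a tibble of distinct undirected edges with 0-based node
#' ids and `node_i < node_j`. Rows are stored in canonical edge order.
#'
#' @param edges A data frame with columns `node_i`, `node_j` (0-based).
#' @param n_nodes Number of atlas nodes the mask lives on.
#' @return A tibble of class `network_mask` with attribute `n_nodes`.
#' @export
network_mask <- function(edges, n_nodes) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  edges <- as_tibble(edges)
  check_columns(edges, c("node_i", "node_j"), "edge table")
  i <- as.integer(edges$node_i)
  j <- as.integer(edges$node_j)
  flip <- i > j
  tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
  if (any(i == j)) abort("self-loops are not valid edges")
  if (any(i < 0) || any(j >= n_nodes)) {
    abort(sprintf("edge node ids must lie in [0, %d]", n_nodes - 1L))
  }
  pos <- edge_position(i, j, n_nodes)
  if (anyDuplicated(pos)) abort("mask contains duplicated edges")
  ord <- order(pos)
  out <- tibble(node_i = i[ord], node_j = j[ord])
  attr(out, "n_nodes") <- n_nodes
  class(out) <- c("network_mask", class(out))
  out
}

#' Randomly plant a subnetwork mask
#'
#' Samples `n_edges` distinct undirected edges over `n_nodes` nodes. The
#' default samples uniformly without replacement from all
#' `n_nodes * (n_nodes - 1) / 2` edges. With `connected = TRUE` the edges
#' form a single connected subnetwork: a random node cluster of the minimal
#' size that can carry `n_edges` with some slack is selected, wired with a
#' random spanning tree, and filled in with uniformly chosen extra edges
#' within the cluster. A connected truth is the appropriate ground truth for
#' component-based inference, which can only ever report connected edge sets.
#'
#' @param n_nodes Number of atlas nodes.
#' @param n_edges Number of edges to plant.
#' @param seed Integer seed; the same seed always yields the same mask.
#' @param connected If `TRUE`, plant a connected subnetwork (see Details).
#' @return A [network_mask()] tibble.
#' @export
#' @examples
#' plant_network(10, 5, seed = 1)
plant_network <- function(n_nodes, n_edges, seed, connected = FALSE) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  n_edges <- check_count(n_edges, "n_edges", min = 1L)
  e_total <- n_edges_for(n_nodes)
  if (n_edges > e_total) {
    abort(sprintf("n_edges (%d) exceeds the %d possible edges on %d nodes",
                  n_edges, e_total, n_nodes))
  }
  idx <- edge_index(n_nodes)
  if (!connected) {
    picked <- with_rng(seed, sample.int(e_total, n_edges))
    return(network_mask(
      tibble(node_i = idx[picked, 1L], node_j = idx[picked, 2L]), n_nodes))
  }
  # Smallest cluster that can carry n_edges with a little slack: the
  # planted subnetwork is a compact, near-clique module, so component-based
  # recovery has a well-defined connected ground truth with few uninvolved
  # within-cluster pairs.
  k <- 2L
  while (n_edges_for(k) < ceiling(1.2 * n_edges) && k < n_nodes) {
    k <- k + 1L
  }
  with_rng(seed, {
    nodes <- sort(sample.int(n_nodes, k) - 1L)
    # Random spanning tree over the cluster (random attachment order).
    ord <- sample(nodes)
    tree <- cbind(ord[-1L], vapply(2:k, function(m) {
      ord[sample.int(m - 1L, 1L)]
    }, integer(1)))
    tree <- cbind(pmin(tree[, 1L], tree[, 2L]), pmax(tree[, 1L], tree[, 2L]))
    pairs <- t(utils::combn(nodes, 2L))
    pos_all <- edge_position(pairs[, 1L], pairs[, 2L], n_nodes)
    pos_tree <- edge_position(tree[, 1L], tree[, 2L], n_nodes)
    extra_pool <- setdiff(pos_all, pos_tree)
    n_extra <- n_edges - (k - 1L)
    pos <- if (n_extra > 0L) {
      c(pos_tree, sample(extra_pool, n_extra))
    } else {
      # n_edges < tree size cannot occur: capacity check forces k - 1 <= n_edges
      pos_tree[seq_len(n_edges)]
    }
    network_mask(tibble(node_i = idx[pos, 1L], node_j = idx[pos, 2L]), n_nodes)
  })
}

# 1-based canonical edge positions of a mask.
mask_edge_ids <- function(mask, n_nodes = attr(mask, "n_nodes")) {
  if (is.null(n_nodes)) abort("mask has no n_nodes attribute; supply n_nodes")
  edge_position(mask$node_i, mask$node_j, n_nodes)
}

#' Jaccard index between two network masks
#'
#' @param a,b Network masks (or plain edge tables) over the same atlas.
#' @param n_nodes Node count; defaults to the masks' attribute.
#' @return Jaccard index |a & b| / |a | b| in \[0, 1\].
#' @export
mask_jaccard <- function(a, b, n_nodes = attr(a, "n_nodes")) {
  ia <- mask_edge_ids(a, n_nodes)
  ib <- mask_edge_ids(b, n_nodes)
  length(intersect(ia, ib)) / length(union(ia, ib))
}
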