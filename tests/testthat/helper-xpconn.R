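# Shared fixtures: small configurations and a cached tiny cohort.

tiny_config <- function(seed = 42, ...) {
  args <- list(n_nodes = 20, n_paradigms = 3, timepoints = 48,
               group_sizes = c(control = 5, nonconverter = 5, converter = 5),
               planted_edge_count = 6, effect_sizes = c(0, 0.5, 1),
               seed = seed)
  do.call(synth_config, modifyList(args, list(...)))
}

# one small cohort reused across read-only tests
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(tiny_config())
    cache
  }
})

std_covariates <- c("age", "sex", "iq", "site", "fd", "dose")

# random scan fixture
random_scan <- function(n_nodes = 8, n_t = 120, n_reg = 3, seed = 1,
                        tr = 2) {
  withr::with_seed(seed, {
    scan_ts(matrix(rnorm(n_nodes * n_t), n_nodes, n_t), "S1", "rest",
            sampling_interval = tr,
            nuisance = if (n_reg > 0) {
              matrix(rnorm(n_t * n_reg), n_t, n_reg,
                     dimnames = list(NULL, paste0("reg", seq_len(n_reg))))
            } else NULL)
  })
}

# independent partition oracle for suprathreshold graphs
igraph_components <- function(node_i, node_j, n_nodes) {
  g <- igraph::graph_from_edgelist(cbind(node_i, node_j) + 1L,
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  igraph::components(g)$membership
}

# canonical form of an edge partition: sorted list of sorted edge-id sets
partition_canonical <- function(edge_ids, comp) {
  sets <- split(sort(edge_ids), comp[order(edge_ids)])
  unname(sets[order(vapply(sets, min, numeric(1)))])
}
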