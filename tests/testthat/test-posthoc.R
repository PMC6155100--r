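# Post-hoc battery: network means, group tests, correlations, effect
# sizes, specificity permutation, ROC transfer.

test_that("network_mean averages mask edges exactly", {
  mask <- network_mask(data.frame(node_i = c(0, 1), node_j = c(1, 2)), 4)
  v <- rep(0, 6)
  ids <- c(1, 4)   # canonical positions of (0,1) and (1,2) on 4 nodes
  v[ids] <- c(0.2, 0.4)
  expect_equal(network_mean(v, mask), 0.3)
  expect_equal(network_mean(rep(0.7, 6), mask), 0.7)
  withr::with_seed(6, {
    y <- matrix(rnorm(5 * 6), 5, 6)
    expect_equal(network_mean(y, mask), rowMeans(y[, ids]),
                 tolerance = 1e-12)
    m <- devectorize_edges(rnorm(6))
    expect_equal(network_mean(m, mask),
                 mean(m[cbind(mask$node_i + 1, mask$node_j + 1)]),
                 tolerance = 1e-12)
  })
  expect_error(network_mean(v, mask[0, ]), "empty")
})

test_that("ancova omnibus equals the textbook one-way ANOVA", {
  withr::with_seed(10, {
    dat <- tibble::tibble(y = rnorm(45),
                          group = rep(c("a", "b", "c"), each = 15))
    ours <- ancova_group_test(dat, "y")
    ref <- anova(lm(y ~ group, dat))
    expect_equal(ours$value, ref["group", "F value"], tolerance = 1e-10)
    expect_equal(ours$p, ref["group", "Pr(>F)"], tolerance = 1e-10)
    dat$y2 <- rep(2, 45)
    flat <- ancova_group_test(dat, "y2")
    expect_equal(flat$value, 0)
    expect_equal(flat$p, 1)
  })
})

test_that("the linear trend test is powered for ordered means", {
  withr::with_seed(12, {
    dat <- tibble::tibble(
      y = c(rnorm(20, 0, 0.1), rnorm(20, 0.5, 0.1), rnorm(20, 1, 0.1)),
      group = factor(rep(c("lo", "mid", "hi"), each = 20),
                     levels = c("lo", "mid", "hi"), ordered = TRUE))
    out <- ancova_group_test(dat, "y", contrast = "linear_trend")
    expect_lt(out$p, 0.001)
    expect_gt(out$value, 0)
  })
})

test_that("paradigm-wise Bonferroni arithmetic is exact", {
  withr::with_seed(13, {
    pm <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:30),
                             paradigm = paste0("p", 1:5))
    pm$value <- rnorm(nrow(pm))
    design <- tibble::tibble(subject_id = sprintf("S%02d", 1:30),
                             group = rep(c("a", "b"), each = 15))
    out <- paradigm_wise_group_tests(pm, design)
    expect_equal(nrow(out), 5)
    expect_equal(out$p_adjusted, pmin(1, 5 * out$p))
    expect_true(all(out$correction == "bonferroni"))
  })
})

test_that("correlations handle monotone pairs, ties, and family correction", {
  expect_equal(correlate_vars(1:8, (1:8)^3, method = "spearman")$value, 1)
  expect_equal(correlate_vars(1:8, -(1:8)^3, method = "spearman")$value, -1)
  # average-rank hand computation with ties
  out <- correlate_vars(c(1, 2, 2, 3), c(1, 3, 2, 4), method = "spearman")
  expect_equal(out$value, 4.5 / sqrt(4.5 * 5), tolerance = 1e-12)
  fam <- correlate_vars(rnorm(20), rnorm(20), fwe_n = 4)
  expect_equal(fam$p_adjusted, min(1, 4 * fam$p))
  expect_error(correlate_vars(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate_vars(1:3, 1:3), ">= 4")
})

test_that("cohens_d matches hand computations and is shift invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(1, 3)), -1 / sqrt(2), tolerance = 1e-12)
  withr::with_seed(14, {
    a <- rnorm(30); b <- rnorm(25, 0.4)
    expect_equal(cohens_d(a + 5, b + 5), cohens_d(a, b), tolerance = 1e-12)
  })
})

test_that("AUC equals the pair-counting and rank-sum forms", {
  out <- roc_transfer(c(0.9, 0.8, 0.85, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                      n_permutations = 100, seed = 1)
  expect_equal(out$auc, 0.75)
  perfect <- roc_transfer(c(1, 2, 3, 10, 11, 12),
                          rep(c(FALSE, TRUE), each = 3),
                          n_permutations = 100, seed = 1)
  expect_equal(perfect$auc, 1)
  withr::with_seed(15, {
    for (i in 1:10) {
      sc <- round(rnorm(40), 1)   # force ties
      lab <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
      if (!any(lab) || all(lab)) next
      ours <- roc_transfer(sc, lab, n_permutations = 100, seed = i)$auc
      w <- suppressWarnings(stats::wilcox.test(sc[lab], sc[!lab]))
      expect_equal(ours, w$statistic[[1]] / (sum(lab) * sum(!lab)),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_transfer(1:4, rep(TRUE, 4), 100, 1), "both classes")
})

test_that("ROC permutation p is valid under the null and small for separation", {
  withr::with_seed(16, {
    p_null <- vapply(1:30, function(i) {
      roc_transfer(rnorm(40), rep(c(TRUE, FALSE), 20),
                   n_permutations = 99, seed = i)$p
    }, numeric(1))
    expect_gt(mean(p_null > 0.05), 0.8)
    sep <- roc_transfer(c(rnorm(20), rnorm(20, 3)),
                        rep(c(FALSE, TRUE), each = 20),
                        n_permutations = 199, seed = 3)
    expect_lte(sep$p, 0.01)
  })
})

test_that("pairwise contrasts count pairs and apply Bonferroni", {
  withr::with_seed(18, {
    dat2 <- tibble::tibble(y = rnorm(20), group = rep(c("a", "b"), 10))
    out2 <- pairwise_posthoc(dat2, "y")
    expect_equal(nrow(out2), 1)
    expect_equal(out2$p_adjusted, out2$p)   # single pair: factor 1
    dat4 <- tibble::tibble(y = rnorm(40), group = rep(letters[1:4], 10))
    out4 <- pairwise_posthoc(dat4, "y")
    expect_equal(nrow(out4), 6)
    expect_equal(out4$p_adjusted, pmin(1, 6 * out4$p))
    # matches pairwise t tests (equal-variance, shared model) for 2 groups
    ref <- t.test(y ~ group, dat2, var.equal = TRUE)
    expect_equal(abs(out2$value), abs(ref$statistic[[1]]), tolerance = 1e-10)
  })
})

test_that("specificity test is degenerate when the mask covers all edges", {
  withr::with_seed(40, {
    y <- matrix(rnorm(12 * 45, mean = 0.3), 12, 45)
    rownames(y) <- sprintf("S%02d", 1:12)
    design <- tibble::tibble(subject_id = rownames(y),
                             group = rep(c("a", "b"), each = 6),
                             age = rnorm(12))
    all_mask <- network_mask(edge_table(10)[, c("node_i", "node_j")], 10)
    out <- edge_specificity_test(y, design, all_mask, covariates = "age",
                                 n_draws = 25, seed = 1)
    # draws permute the summation order only; means agree to rounding
    expect_true(all(abs(out$null_p - out$observed_p) < 1e-8))
  })
})

test_that("specificity test separates a planted mask from random draws", {
  cfg <- tiny_config(n_nodes = 30, planted_edge_count = 10, timepoints = 80,
                     group_sizes = c(control = 20, converter = 20),
                     effect_sizes = c(0, 1.5), seed = 77)
  co <- generate_cohort(cfg)
  tr <- cohort_trait_edges(co)
  out <- edge_specificity_test(tr$trait, co$design, co$truth$mask,
                               covariates = std_covariates,
                               n_draws = 200, seed = 2)
  expect_lt(out$observed_p, quantile(out$null_p, 0.05))
  expect_lte(out$rank, 10)
})

test_that("pairwise contrasts are labeled correctly for ordered groups", {
  withr::with_seed(19, {
    g <- factor(rep(c("lo", "mid", "hi"), each = 25),
                levels = c("lo", "mid", "hi"), ordered = TRUE)
    dat <- tibble::tibble(y = c(rnorm(25, 0), rnorm(25, 1), rnorm(25, 2)),
                          group = g)
    out <- pairwise_posthoc(dat, "y")
    est <- setNames(out$estimate, out$test)
    expect_equal(unname(est["pairwise:hi-lo"]),
                 mean(dat$y[g == "hi"]) - mean(dat$y[g == "lo"]),
                 tolerance = 1e-10)
    expect_gt(est["pairwise:hi-lo"], est["pairwise:mid-lo"])
  })
})
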