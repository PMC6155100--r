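# Edge-wise GLM, component formation, and the NBS permutation test.

test_that("edge-wise F equals the classic one-way ANOVA", {
  withr::with_seed(1, {
    y <- matrix(rnorm(40 * 10), 40, 10)
    design <- tibble::tibble(subject_id = sprintf("S%02d", 1:40),
                             group = rep(c("a", "b"), each = 20))
    rownames(y) <- design$subject_id
    out <- edgewise_glm(y, design)
    # hand formula for two groups
    for (e in c(1, 5, 10)) {
      v <- y[, e]
      g <- design$group
      ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - mean(v))^2))
      ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
      f_hand <- (ssb / 1) / (ssw / 38)
      expect_equal(out$statistic[e], f_hand, tolerance = 1e-10)
    }
    # and against anova(lm()) with covariates
    design$age <- rnorm(40)
    out2 <- edgewise_glm(y, design, covariates = "age")
    fit <- lm(y[, 3] ~ age + group, data = design)
    f_lm <- anova(fit)["group", "F value"]
    expect_equal(out2$statistic[3], f_lm, tolerance = 1e-10)
  })
})

test_that("identical groups give F = 0 everywhere", {
  y <- matrix(rep(rnorm(10), each = 12), 12, 10)
  design <- tibble::tibble(subject_id = sprintf("S%02d", 1:12),
                           group = rep(c("a", "b", "c"), each = 4))
  rownames(y) <- design$subject_id
  out <- edgewise_glm(y, design)
  expect_equal(out$statistic, rep(0, 10))
  expect_equal(out$p, rep(1, 10))
})

test_that("a group difference fully mediated by a covariate vanishes", {
  withr::with_seed(2, {
    cov_var <- c(rnorm(25, 0), rnorm(25, 4))
    y <- matrix(cov_var + rnorm(150), 50, 3)
    design <- tibble::tibble(subject_id = sprintf("S%02d", 1:50),
                             group = rep(c("a", "b"), each = 25),
                             x = cov_var)
    rownames(y) <- design$subject_id
    raw <- edgewise_glm(y, design)
    adj <- edgewise_glm(y, design, covariates = "x")
    expect_gt(min(raw$statistic), 30)
    # after adjustment the group F is an ordinary null statistic
    expect_lt(max(adj$statistic), qf(1 - 1e-3, 1, 47))
  })
})

test_that("rank-deficient designs are refused with the collinear column named", {
  design <- tibble::tibble(subject_id = sprintf("S%02d", 1:20),
                           group = rep(c("a", "b"), each = 10),
                           x1 = rnorm(20))
  design$x2 <- 2 * design$x1
  y <- matrix(rnorm(40), 20, 2, dimnames = list(design$subject_id, NULL))
  expect_error(edgewise_glm(y, design, covariates = c("x1", "x2")), "x2")
})

test_that("component formation matches hand-worked examples", {
  et <- edge_table(6)
  et$statistic <- 0
  et$p <- 1
  mark <- function(i, j) which(et$node_i == i & et$node_j == j)
  hot <- c(mark(1, 2), mark(2, 3), mark(4, 5))
  et$p[hot] <- 1e-6
  comp <- threshold_components(et, threshold_p = 0.001)
  expect_equal(nrow(comp), 3)
  expect_equal(max(comp$size), 2)
  expect_equal(sort(unique(comp$size)), c(1, 2))
  # empty suprathreshold set
  et$p <- 1
  expect_equal(nrow(threshold_components(et)), 0)
})

test_that("component partition agrees with the igraph oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(3, {
    for (i in 1:200) {
      n <- sample(5:50, 1)
      et <- edge_table(n)
      et$statistic <- rnorm(nrow(et))
      et$p <- runif(nrow(et))
      thr <- runif(1, 0.02, 0.3)
      comp <- threshold_components(et, threshold_p = thr)
      sub <- et[et$p < thr, ]
      if (nrow(sub) == 0) {
        expect_equal(nrow(comp), 0)
        next
      }
      memb <- igraph_components(sub$node_i, sub$node_j, n)
      oracle_comp <- memb[sub$node_i + 1L]
      expect_identical(partition_canonical(comp$edge, comp$component),
                       partition_canonical(sub$edge, oracle_comp))
    }
  })
})

test_that("nbs_test is deterministic and invariant to subject order", {
  co <- tiny_cohort()
  tr <- cohort_trait_edges(co)
  run <- function(y, d) nbs_test(y, d, covariates = c("age", "fd"),
                                 threshold_p = 0.01, n_permutations = 120,
                                 seed = 7)
  a <- run(tr$trait, co$design)
  b <- run(tr$trait, co$design)
  expect_identical(a$null_max, b$null_max)
  expect_identical(tidy(a), tidy(b))
  perm <- withr::with_seed(1, sample(nrow(tr$trait)))
  c_ <- run(tr$trait[perm, ], co$design[perm, ])
  expect_identical(a$null_max, c_$null_max)
  expect_equal(a$edge_stats$statistic, c_$edge_stats$statistic)
  expect_identical(as.data.frame(a$winning_mask), as.data.frame(c_$winning_mask))
})

test_that("FWE p is monotone in the component statistic", {
  co <- tiny_cohort()
  tr <- cohort_trait_edges(co)
  nb <- nbs_test(tr$trait, co$design, covariates = c("age", "fd"),
                 threshold_p = 0.05, n_permutations = 150, seed = 2)
  cmp <- nb$components
  if (nrow(cmp) >= 2) {
    ord <- order(cmp$statistic)
    expect_true(all(diff(cmp$fwe_p[ord]) <= 0))
  }
  expect_true(all(cmp$fwe_p > 0 & cmp$fwe_p <= 1))
  # intensity statistic runs and reports sums of suprathreshold excess
  nb2 <- nbs_test(tr$trait, co$design, covariates = c("age", "fd"),
                  threshold_p = 0.05, n_permutations = 100, seed = 2,
                  statistic = "intensity")
  if (nrow(nb2$components) > 0) {
    expect_true(all(nb2$components$statistic > 0))
  }
})

test_that("glance reports the headline numbers", {
  co <- tiny_cohort()
  tr <- cohort_trait_edges(co)
  nb <- nbs_test(tr$trait, co$design, covariates = c("age", "fd"),
                 threshold_p = 0.01, n_permutations = 100, seed = 9)
  gl <- glance(nb)
  expect_equal(gl$n_permutations, 100)
  expect_equal(gl$threshold_p, 0.01)
  expect_equal(gl$n_subjects, nrow(co$design))
})
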