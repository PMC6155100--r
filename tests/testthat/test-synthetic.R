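# Synthetic cohort generator: configuration validation, determinism,
# structural invariants, and statistical calibration.

test_that("configuration validation catches contract violations", {
  expect_error(synth_config(group_sizes = c(a = 1, b = 5)), ">= 2")
  expect_error(synth_config(effect_sizes = c(1, 0.5, 0)), "monotone")
  expect_error(synth_config(shared_variance_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(planted_edge_count = 1e6), "exceeds")
  expect_error(synth_config(effect_sizes = c(0, 1)), "one entry per group")
  # non-graded mode admits non-monotone effects
  expect_s3_class(synth_config(effect_sizes = c(1, 0, 0.5), graded = FALSE),
                  "synth_config")
})

test_that("identical config and seed give a bit-identical cohort", {
  a <- generate_cohort(tiny_config())
  b <- generate_cohort(tiny_config())
  expect_identical(lapply(a$scans, `[[`, "data"),
                   lapply(b$scans, `[[`, "data"))
  expect_identical(a$design, b$design)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$delta_z, b$truth$delta_z)
})

test_that("full sharing and zero noise give identical matrices across paradigms", {
  co <- generate_cohort(tiny_config(shared_variance_fraction = 1,
                                    noise_sd = 0))
  for (s in unique(co$scan_index$subject_id)[1:3]) {
    cs <- lapply(co$scans[co$scan_index$scan[co$scan_index$subject_id == s]],
                 compute_connectivity)
    for (i in seq_along(cs)[-1]) {
      expect_identical(unclass(cs[[1]]), unclass(cs[[i]]))
    }
  }
})

test_that("cohort structure honours its contracts", {
  co <- tiny_cohort()
  idx <- co$scan_index
  expect_true(all(table(idx$subject_id) >= 2))
  ph <- co$phenotypes
  conv <- !is.na(ph$months_to_conversion)
  expect_true(all(ph$months_to_conversion[conv] > 0))
  expect_true(all(ph$follow_up_months[conv] >= ph$months_to_conversion[conv]))
  expect_setequal(ph$subject_id, co$design$subject_id)
  m <- co$truth$mask
  expect_true(all(m$node_i < m$node_j))
  # paradigm dropout keeps at least two paradigms
  co2 <- generate_cohort(tiny_config(dropout_prob = 0.5))
  expect_true(all(table(co2$scan_index$subject_id) >= 2))
})

test_that("null effect sizes leave no group shift on the planted edges", {
  d <- vapply(1:15, function(i) {
    cfg <- tiny_config(n_nodes = 24, timepoints = 60, n_paradigms = 2,
                       group_sizes = c(control = 12, converter = 12),
                       effect_sizes = c(0, 0), planted_edge_count = 8,
                       seed = 900 + i)
    co <- generate_cohort(cfg)
    tr <- cohort_trait_edges(co, regress = FALSE)
    cz <- atanh(pmin(pmax(tr$connectivity, -1 + 1e-9), 1 - 1e-9))
    pm <- tapply(network_mean(cz, co$truth$mask), co$scan_index$subject_id,
                 mean)[co$design$subject_id]
    g <- co$design$group
    cohens_d(pm[g == "converter"], pm[g == "control"])
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.2)
})

test_that("requested graded effects are realized within tolerance", {
  d <- vapply(1:8, function(i) {
    cfg <- synth_config(n_paradigms = 3, timepoints = 120,
                        group_sizes = c(control = 40, nonconverter = 40,
                                        converter = 40),
                        effect_sizes = c(0, 0.5, 1), seed = 200 + i)
    co <- generate_cohort(cfg)
    tr <- cohort_trait_edges(co, regress = FALSE)
    cz <- atanh(pmin(pmax(tr$connectivity, -1 + 1e-9), 1 - 1e-9))
    pm <- tapply(network_mean(cz, co$truth$mask), co$scan_index$subject_id,
                 mean)[co$design$subject_id]
    g <- co$design$group
    cohens_d(pm[g == "converter"], pm[g == "control"])
  }, numeric(1))
  expect_lt(abs(mean(d) - 1), 0.25)
})

test_that("first-PC variance explained grows monotonically with sharing", {
  ve <- vapply(c(0.2, 0.5, 0.8, 1), function(f) {
    cfg <- synth_config(n_paradigms = 3, timepoints = 80,
                        group_sizes = c(a = 8, b = 8),
                        effect_sizes = c(0, 0), graded = FALSE,
                        shared_variance_fraction = f, seed = 3)
    mean(cohort_trait_edges(generate_cohort(cfg),
                            regress = FALSE)$pca$variance_explained_1)
  }, numeric(1))
  expect_true(all(diff(ve) > 0))
})

test_that("phenotypes carry the configured coupling sign", {
  hits <- vapply(1:12, function(i) {
    cfg <- synth_config(n_nodes = 40, n_paradigms = 2, timepoints = 60,
                        group_sizes = c(control = 33, nonconverter = 33,
                                        converter = 34),
                        phenotype_coupling = 0.5, seed = 500 + i)
    co <- generate_cohort(cfg)
    s <- co$truth$planted_strength
    conv <- co$design$group == "converter"
    c(cor(s, co$phenotypes$symptom_disorganization, method = "spearman") > 0,
      cor(s[conv], co$phenotypes$months_to_conversion[conv],
          method = "spearman") < 0)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})
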