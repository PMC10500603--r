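test_that("generators are fully deterministic under a seed", {
  ac <- synthetic_atlas_config(n_regions = 15, n_genes = 400,
                               target_set_size = 25, seed = 99)
  s1 <- make_atlas(ac)
  s2 <- make_atlas(ac)
  expect_identical(s1$atlas$exprs, s2$atlas$exprs)
  expect_identical(s1$gene_set$gene, s2$gene_set$gene)
  s3 <- make_atlas(synthetic_atlas_config(n_regions = 15, n_genes = 400,
                                          target_set_size = 25, seed = 100))
  expect_false(identical(s1$atlas$exprs, s3$atlas$exprs))

  cc <- synthetic_cohort_config(n_per_group = 25, seed = 7)
  expect_identical(make_cohort(cc), make_cohort(cc))
  expect_false(identical(
    make_cohort(cc),
    make_cohort(synthetic_cohort_config(n_per_group = 25, seed = 8))))
})

test_that("synthetic cohorts respect the participant invariants", {
  coh <- make_cohort(synthetic_cohort_config(seed = 3))
  expect_equal(nrow(coh), 222)
  expect_equal(sum(coh$group == "case"), 111)
  expect_true(all(coh$age > 0))
  expect_true(all(coh$icv > 0))
  expect_true(all(coh$vol_roi > 0))
  dx_cols <- grep("^dx_", names(coh), value = TRUE)
  expect_length(dx_cols, 8)
  for (col in dx_cols) {
    expect_true(all(coh[[col]] %in% c("absent", "past", "current")))
  }
  expect_equal(anyDuplicated(coh$id), 0)
})

test_that("planted diagnosis prevalences are honoured on average", {
  counts <- vapply(1:30, function(i) {
    coh <- make_cohort(synthetic_cohort_config(n_per_group = 111, seed = i))
    c(sum(coh$dx_obsessive_compulsive == "current" & coh$group == "case"),
      sum(coh$dx_obsessive_compulsive == "current" & coh$group == "control"))
  }, numeric(2))
  expect_lt(abs(mean(counts[1, ]) - 0.22 * 111), 3)
  expect_lt(abs(mean(counts[2, ]) - 0.07 * 111), 3)
})

test_that("region sampling thins the shared region universe", {
  sim <- make_atlas(synthetic_atlas_config(
    n_regions = 40, n_genes = 300, target_set_size = 20,
    region_sampling_rate = 0.7, seed = 12))
  per_donor <- vapply(sim$atlas$exprs, ncol, integer(1))
  expect_true(all(per_donor < 40))
  universe <- region_universe(sim$atlas, 5)
  expect_lt(nrow(universe), 40)
  expect_error(
    synthetic_atlas_config(planted_regions = "region_999"),
    "not in the region list")
})

test_that("matched null counterparts are bit-exact shift-0 draws", {
  ac <- synthetic_atlas_config(n_regions = 12, n_genes = 300,
                               target_set_size = 20, planted_shift = 0.7,
                               region_sampling_rate = 0.9, seed = 21)
  sim <- make_atlas(ac)
  ac0 <- ac; ac0$planted_shift <- 0
  expect_identical(make_null_counterpart(sim)$atlas$exprs,
                   make_atlas(ac0)$atlas$exprs)
})

test_that("matched-null ROI evaluation equals the materialised null path", {
  ac <- synthetic_atlas_config(n_regions = 20, n_genes = 900,
                               target_set_size = 35, planted_shift = 0.8,
                               region_sampling_rate = 0.85, seed = 44)
  sim <- make_atlas(ac)
  atl <- normalize_within_donor(sim$atlas)
  fast <- suppressMessages(
    get_rois_matched_null(sim, atl, min_freq = 1, min_donors = 4))
  slow <- suppressMessages(get_rois(
    normalize_within_donor(make_null_counterpart(sim)$atlas),
    sim$gene_set, min_freq = 1, min_donors = 4))
  expect_equal(tibble::as_tibble(fast), tibble::as_tibble(slow),
               tolerance = 1e-12)
})

test_that("pipeline recovery holds under a log-normal background", {
  sim <- make_atlas(synthetic_atlas_config(
    n_regions = 30, n_genes = 2000, target_set_size = 93,
    planted_shift = 1, background = "lognormal", seed = 66))
  atl <- normalize_within_donor(sim$atlas)
  rois <- get_rois(atl, sim$gene_set)
  expect_equal(rois$region[1], "region_001")
  expect_equal(rois$frequency[1], 6L)
})

test_that("the recovery suite summarises planted-parameter recovery", {
  out <- recovery_suite(
    synthetic_atlas_config(n_regions = 25, n_genes = 1500,
                           target_set_size = 93, planted_shift = 1),
    synthetic_cohort_config(n_per_group = 60),
    n_replicates = 10, seed = 5)
  expect_true(all(c("metric", "value", "n_replicates") %in% names(out)))
  expect_equal(out$value[out$metric == "planted_region_recovery_rate"], 1)
  expect_equal(out$value[out$metric == "null_false_positive_rate"], 0)
  bias <- out$value[grepl("^slope_bias_", out$metric)]
  rmse <- out$value[grepl("^slope_rmse_", out$metric)]
  expect_true(all(abs(bias) <= rmse))
  expect_error(
    recovery_suite(synthetic_atlas_config(), synthetic_cohort_config(),
                   n_replicates = 5, seed = 1),
    ">= 10")
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_atlas_config(n_genes = 50, target_set_size = 50),
               "smaller")
  expect_error(synthetic_atlas_config(planted_shift = -1), ">= 0")
  expect_error(synthetic_atlas_config(region_sampling_rate = 0),
               "rate")
  expect_error(
    synthetic_cohort_config(diagnosis_prevalences = list(a = c(1.2, 0.5))),
    "\\[0, 1\\]")
  expect_error(synthetic_cohort_config(n_per_group = 2), ">= 3")
})
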