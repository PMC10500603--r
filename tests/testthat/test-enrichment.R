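small_planted_sim <- function(seed = 7, shift = 1, n_regions = 40,
                              n_genes = 2000, set_size = 93) {
  make_atlas(synthetic_atlas_config(
    n_donors = 6, n_regions = n_regions, n_genes = n_genes,
    target_set_size = set_size, planted_shift = shift, seed = seed))
}

test_that("single-region enrichment test matches hand enumeration", {
  m <- matrix(c(1, 2, 3, 4), nrow = 1,
              dimnames = list("roi", c("B1", "B2", "T1", "T2")))
  res <- region_enrichment_test(m, "roi", c("T1", "T2"))
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)
  expect_equal(res$direction, 1)

  tied <- matrix(c(1, 2, 1, 2), nrow = 1,
                 dimnames = list("roi", c("B1", "B2", "T1", "T2")))
  res2 <- region_enrichment_test(tied, "roi", c("T1", "T2"))
  expect_equal(res2$p, 1)

  expect_error(region_enrichment_test(m, "missing", c("T1", "T2")),
               "not found")
  expect_error(region_enrichment_test(m, "roi", "T1"), "< 2 members")
})

test_that("a planted shift among 20,000 genes is overwhelming", {
  set.seed(42)
  genes <- sprintf("G%05d", 1:20000)
  values <- rnorm(20000)
  targets <- sample(genes, 93)
  values[genes %in% targets] <- values[genes %in% targets] + 1
  m <- matrix(values, nrow = 1, dimnames = list("roi", genes))
  res <- region_enrichment_test(m, "roi", targets)
  expect_lt(res$p, 1e-6)
  expect_equal(res$direction, 1)
})

test_that("Bonferroni adjustment uses the explicit family size", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 1), 0.5)
  expect_equal(bonferroni_adjust(0.4, 10), 1)
  expect_equal(bonferroni_adjust(c(0.001, 0.02), 30), c(0.03, 0.6))
  expect_error(bonferroni_adjust(0.1, 0), ">= 1")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least the number")
  expect_error(bonferroni_adjust(1.2, 5), "0, 1")
})

test_that("get_rois recovers a planted region and agrees with the scalar test", {
  sim <- small_planted_sim()
  atl <- normalize_within_donor(sim$atlas)
  rois <- get_rois(atl, sim$gene_set)
  expect_equal(rois$region[1], "region_001")
  expect_equal(rois$frequency[1], 6L)
  expect_equal(rois$rank[1], 1L)
  expect_gt(rois$effect_summary[1], 0.5)

  # per-donor p-values equal the scalar per-region engine
  details <- tidy(rois)
  for (d in c("donor1", "donor4")) {
    scalar <- region_enrichment_test(t(atl$exprs[[d]]), "region_001",
                                     sim$gene_set)
    row <- details[details$donor == d & details$region == "region_001", ]
    expect_equal(row$p, scalar$p, tolerance = 1e-12)
    expect_equal(row$direction, scalar$direction)
  }
})

test_that("roi sets are empty when the frequency filter is unsatisfiable", {
  sim <- small_planted_sim(seed = 3)
  atl <- normalize_within_donor(sim$atlas)
  expect_message(
    rois <- get_rois(atl, sim$gene_set, min_freq = 7),
    "empty ROI set")
  expect_equal(nrow(rois), 0)
})

test_that("results are invariant to gene and donor permutations", {
  sim <- small_planted_sim(seed = 12, n_regions = 20, n_genes = 600,
                           set_size = 40)
  atl <- normalize_within_donor(sim$atlas)
  base <- get_rois(atl, sim$gene_set, min_freq = 4)

  set.seed(1)
  row_perm <- sample(nrow(atl$exprs[[1]]))  # shared gene order across donors
  perm_exprs <- lapply(rev(atl$exprs), function(m) {
    m[row_perm, , drop = FALSE]
  })
  atl_perm <- pglr:::new_atlas(perm_exprs, normalized = TRUE)
  perm <- get_rois(atl_perm, sim$gene_set, min_freq = 4)
  expect_equal(
    dplyr::select(tibble::as_tibble(base), -"per_donor"),
    dplyr::select(tibble::as_tibble(perm), -"per_donor"))
})

test_that("counting kernel and precomputed-rank paths agree, ties included", {
  sim <- small_planted_sim(seed = 21, n_regions = 15, n_genes = 500,
                           set_size = 30, shift = 0.8)
  # round to one decimal to force heavy ties through both code paths
  sim$atlas$exprs <- lapply(sim$atlas$exprs, round, digits = 1)
  atl <- normalize_within_donor(sim$atlas)
  counting <- suppressMessages(get_rois(atl, sim$gene_set, min_freq = 0))
  precompute_ranks(atl)
  cached <- suppressMessages(get_rois(atl, sim$gene_set, min_freq = 0))
  expect_equal(tibble::as_tibble(counting), tibble::as_tibble(cached),
               tolerance = 1e-12)

  # and both agree with the scalar engine on a tied region
  scalar <- region_enrichment_test(t(atl$exprs$donor2), "region_003",
                                   sim$gene_set)
  row <- tidy(counting)
  row <- row[row$donor == "donor2" & row$region == "region_003", ]
  expect_equal(row$p, scalar$p, tolerance = 1e-12)
})

test_that("planted-signal recovery is monotone in the shift", {
  freqs <- vapply(c(0.25, 0.5, 1.0), function(shift) {
    sim <- small_planted_sim(seed = 500, shift = shift)
    atl <- normalize_within_donor(sim$atlas)
    rois <- suppressMessages(get_rois(atl, sim$gene_set, min_freq = 1))
    if ("region_001" %in% rois$region) {
      rois$frequency[rois$region == "region_001"]
    } else 0L
  }, integer(1))
  expect_true(all(diff(freqs) >= 0))
  expect_equal(freqs[3], 6L)
})

test_that("family-wise error is controlled on null atlases", {
  # single-donor null atlases: the chance that any region passes Bonferroni
  # (either direction) should be <= alpha up to binomial noise
  n_rep <- 60
  hits <- vapply(seq_len(n_rep), function(i) {
    sim <- make_atlas(synthetic_atlas_config(
      n_donors = 1, n_regions = 60, n_genes = 800, target_set_size = 40,
      planted_shift = 0, seed = 9000 + i))
    atl <- normalize_within_donor(sim$atlas)
    rois <- suppressMessages(get_rois(atl, sim$gene_set, min_freq = 1,
                                      min_donors = 1))
    nrow(rois) > 0
  }, logical(1))
  rate <- mean(hits)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, bound)
})

test_that("roi ranking orders by frequency, then score, then name", {
  results <- tibble::tibble(
    region = c("b", "a", "c"),
    frequency = c(5L, 6L, 5L),
    score = c(8, 1, 3)
  )
  ranked <- rank_rois(results)
  expect_equal(ranked$region, c("a", "b", "c"))
  expect_equal(ranked$rank, 1:3)

  tiebreak <- rank_rois(tibble::tibble(
    region = c("z", "y"), frequency = c(5L, 5L), score = c(2, 2)))
  expect_equal(tiebreak$region, c("y", "z"))
  expect_equal(rank_rois(tibble::tibble(region = "solo", frequency = 6L,
                                        score = 1))$rank, 1L)
})
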