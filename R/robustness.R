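# Robustness suite: randomized split-half re-analysis and random-gene-list
# false-positive calibration.

#' Split-half validation of an ROI analysis
#'
#' Randomly partitions the gene set into halves of size ceiling(n/2) and
#' floor(n/2), runs [get_rois()] on each half independently, and reports
#' the regions returned by both.  A stable top region reappearing in both
#' halves supports the full-set result.
#'
#' @param atlas Normalised `pgl_atlas`.
#' @param gene_set A [gene_set()] or character vector with at least 4
#'   genes.
#' @param seed Integer seed controlling the partition.
#' @param include_full Also evaluate the full gene set in the same sweep
#'   and return it as `rois_full` (the three evaluations share one pass
#'   over the atlas).
#' @param ... Passed on to [get_rois()] (`alpha`, `min_freq`,
#'   `min_donors`).
#' @return List with `rois_a`, `rois_b` (two `pgl_rois` tibbles),
#'   `overlap` (character vector of shared regions), the two half gene
#'   lists, and `rois_full` when requested.
#' @export
split_half_validation <- function(atlas, gene_set, seed,
                                  include_full = FALSE, ...) {
  genes <- if (inherits(gene_set, "pgl_gene_set")) gene_set$gene else
    toupper(as.character(gene_set))
  n <- length(genes)
  if (n < 4) abort("Gene set must have at least 4 genes to split.")
  seed <- assert_seed(seed)
  perm <- withr::with_seed(seed, sample.int(n))
  n_a <- ceiling(n / 2)
  half_a <- genes[sort(perm[seq_len(n_a)])]
  half_b <- genes[sort(perm[(n_a + 1):n])]
  sets <- list(half_a, half_b)
  if (include_full) sets <- c(sets, list(genes))
  res <- get_rois_sets(atlas, sets, ...)
  out <- list(
    rois_a = res[[1]],
    rois_b = res[[2]],
    overlap = intersect(res[[1]]$region, res[[2]]$region),
    half_a = half_a,
    half_b = half_b,
    seed = seed
  )
  if (include_full) out$rois_full <- res[[3]]
  out
}

#' Random-gene-list false-positive calibration
#'
#' Draws `n_lists` random gene lists of each requested size from the atlas
#' gene universe, runs [get_rois()] on every list, and counts how many
#' lists yield at least one ROI.  On a null atlas this estimates the
#' false-positive rate of the whole Bonferroni + donor-frequency
#' construction.
#'
#' @param atlas Normalised `pgl_atlas`.
#' @param list_sizes Integer vector of list sizes (default 30, 100, 300).
#' @param n_lists Number of random lists per size (default 100).
#' @param seed Master seed; per-list child seeds are spawned
#'   deterministically so single lists can be replayed.
#' @param ... Passed on to [get_rois()].
#' @return A `pgl_fp` tibble: `list_size`, `n_lists`, `n_lists_with_roi`,
#'   `seed`.
#' @export
false_positive_simulation <- function(atlas, list_sizes = c(30L, 100L, 300L),
                                      n_lists = 100L, seed, ...) {
  stopifnot(inherits(atlas, "pgl_atlas"))
  seed <- assert_seed(seed)
  universe_size <- length(atlas$gene_universe)
  if (any(list_sizes > universe_size)) {
    abort(sprintf("List size(s) %s exceed the gene universe (%d genes).",
                  paste(list_sizes[list_sizes > universe_size],
                        collapse = ", "), universe_size))
  }
  if (any(list_sizes < 2)) abort("List sizes must be >= 2.")
  n_lists <- as.integer(n_lists)
  if (n_lists * length(list_sizes) > 1) precompute_ranks(atlas)

  out <- purrr::map_dfr(seq_along(list_sizes), function(i) {
    size <- as.integer(list_sizes[[i]])
    hits <- 0L
    if (n_lists > 0) {
      seeds <- child_seeds(seed + i - 1L, n_lists)
      for (s in seeds) {
        genes <- withr::with_seed(
          s, sample(atlas$gene_universe, size, replace = FALSE))
        rois <- suppressMessages(get_rois(atlas, genes, ...))
        hits <- hits + as.integer(nrow(rois) > 0)
      }
    }
    tibble::tibble(list_size = size, n_lists = n_lists,
                   n_lists_with_roi = hits, seed = seed)
  })
  class(out) <- c("pgl_fp", class(out))
  out
}
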