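# Region-of-interest identification: per-region rank-sum enrichment of a
# gene set against all other genes, Bonferroni control over the region
# universe, aggregation across donors into ranked ROIs.

#' Test one region for gene-set enrichment in one donor
#'
#' Two-sided Wilcoxon rank-sum test comparing the region's (normalised)
#' expression of the target genes against all other genes measured in that
#' donor, plus the direction of the mean difference.
#'
#' @param donor_matrix Normalised region-by-gene matrix for one donor
#'   (regions in rows, genes in columns).
#' @param region Region identifier (row name).
#' @param gene_set A [gene_set()] or character vector of gene symbols.
#' @return List with `p` (two-sided), `direction` (sign of mean target
#'   minus mean background expression) and `delta` (that mean difference).
#' @export
region_enrichment_test <- function(donor_matrix, region, gene_set) {
  genes <- if (inherits(gene_set, "pgl_gene_set")) gene_set$gene else
    toupper(as.character(gene_set))
  if (!region %in% rownames(donor_matrix)) {
    abort(sprintf("Region '%s' not found in the donor matrix.", region))
  }
  values <- donor_matrix[region, ]
  is_target <- colnames(donor_matrix) %in% genes & !is.na(values)
  is_background <- !colnames(donor_matrix) %in% genes & !is.na(values)
  if (sum(is_target) < 2) {
    abort("Gene set intersects the donor's measured genes in < 2 members.")
  }
  if (sum(is_background) < 1) {
    abort("Background (all other genes) is empty.")
  }
  res <- ranksum_engine(values[is_target], values[is_background])
  list(p = res$p, direction = res$direction, delta = res$delta)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, m * p)` per value, order preserved.  Unlike
#' `p.adjust(..., "bonferroni")`, the family size `m` is explicit because
#' the correction is for the number of regions in the shared region
#' universe, which can exceed the number of p-values actually supplied
#' (e.g. a donor missing some universe regions).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Family size, `>= length(p_values)` and `>= 1`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (!is_number(m) || m < 1) abort("`m` must be a single integer >= 1.")
  if (m < length(p_values)) {
    abort("`m` must be at least the number of p-values.")
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  pmin(1, m * p_values)
}

# Vectorised per-donor enrichment of one or more gene sets over a set of
# regions.  Uses precomputed rank matrices when the atlas carries them
# (many-list workloads), otherwise the one-pass counting kernel.  Returns a
# tibble: set, region, p, adj_p, direction, delta.
donor_enrichment <- function(atlas, donor, target_idx_list, regions,
                             m_tests, override = NULL) {
  m <- atlas$exprs[[donor]]
  keep <- colnames(m) %in% regions
  if (!any(keep)) return(NULL)
  key <- paste0("ranks_", donor)
  if (is.null(override) && !is.null(atlas$cache[[key]])) {
    rk <- atlas$cache[[key]]
    cols <- colnames(m)[keep]
    N <- unname(rk$n_obs[cols])
    tie_term <- unname(rk$tie_term[cols])
    s_all <- unname(rk$s_all[cols])
    per_set <- lapply(target_idx_list, function(idx) {
      tr <- rk$ranks[idx, cols, drop = FALSE]
      list(W = unname(colSums(tr, na.rm = TRUE)),
           n1 = unname(colSums(!is.na(tr))),
           s_target = unname(colSums(m[idx, cols, drop = FALSE],
                                     na.rm = TRUE)))
    })
  } else {
    sub <- if (all(keep)) m else m[, keep, drop = FALSE]
    cols <- colnames(sub)
    ov <- if (!is.null(override)) {
      list(rows = as.integer(override$rows),
           values = override$values[, cols, drop = FALSE])
    } else NULL
    en <- .col_enrich_cpp(sub, lapply(target_idx_list, as.integer), ov)
    N <- en$n_obs
    tie_term <- en$tie_term
    s_all <- en$s_all
    per_set <- lapply(seq_along(target_idx_list), function(k) {
      list(W = en$W[, k], n1 = en$n1[, k], s_target = en$s_target[, k])
    })
  }
  dplyr::bind_rows(lapply(seq_along(per_set), function(k) {
    res <- per_set[[k]]
    n1 <- res$n1
    n2 <- N - n1
    U <- res$W - n1 * (n1 + 1) / 2
    p <- ranksum_p(U, n1, n2, N, tie_term)
    delta <- res$s_target / n1 - (s_all - res$s_target) / n2
    delta[n1 == 0 | n2 == 0] <- 0
    tibble::tibble(
      set = k,
      region = cols,
      donor = donor,
      p = p,
      adj_p = bonferroni_adjust(p, m_tests),
      direction = sign(delta),
      delta = delta
    )
  }))
}

# Shared core: evaluate several gene sets against the same atlas in one
# sweep.  Returns a list of pgl_rois, one per set.
get_rois_sets <- function(atlas, gene_sets, alpha = 0.05, min_freq = 5L,
                          min_donors = 5L, null_override = NULL) {
  stopifnot(inherits(atlas, "pgl_atlas"))
  if (!atlas$normalized) {
    abort("Atlas must be normalised first; see normalize_within_donor().")
  }
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  target_idx_list <- lapply(gene_sets, function(gs) {
    genes <- if (inherits(gs, "pgl_gene_set")) gs$gene else
      toupper(as.character(gs))
    idx <- which(atlas$gene_universe %in% genes)
    if (length(idx) < 2) {
      abort("Gene set intersects the atlas gene universe in < 2 genes.")
    }
    idx
  })
  min_donors <- min(as.integer(min_donors), length(atlas$donors))
  universe <- region_universe(atlas, min_donors)
  m_tests <- nrow(universe)

  per_donor <- dplyr::bind_rows(lapply(atlas$donors, function(d) {
    donor_enrichment(
      atlas, d, target_idx_list, universe$region, m_tests,
      override = if (!is.null(null_override)) {
        list(rows = null_override$rows,
             values = null_override$values[[d]])
      } else NULL)
  }))

  lapply(seq_along(gene_sets), function(k) {
    counted <- per_donor |>
      dplyr::filter(.data$set == k) |>
      dplyr::select(-"set") |>
      dplyr::mutate(counts = .data$adj_p < alpha & .data$direction > 0)
    summary <- counted |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        frequency = sum(.data$counts),
        effect_summary = if (any(.data$counts))
          mean(.data$delta[.data$counts]) else NA_real_,
        score = if (any(.data$counts))
          mean(-log10(pmax(.data$adj_p[.data$counts], 1e-300))) else
            NA_real_,
        .groups = "drop"
      ) |>
      dplyr::filter(.data$frequency >= min_freq)

    if (nrow(summary) == 0) {
      inform(
        "No region reaches the requested donor frequency; empty ROI set.")
    }
    details <- counted |>
      tidyr::nest(per_donor = c("donor", "p", "adj_p", "direction", "delta",
                                "counts"))
    out <- summary |>
      dplyr::left_join(details, by = "region") |>
      rank_rois() |>
      dplyr::select("region", "frequency", "rank", "effect_summary",
                    "score", "per_donor")
    attr(out, "alpha") <- alpha
    attr(out, "min_freq") <- as.integer(min_freq)
    attr(out, "min_donors") <- min_donors
    attr(out, "m_tests") <- m_tests
    attr(out, "n_donors") <- length(atlas$donors)
    attr(out, "n_targets_in_universe") <- length(target_idx_list[[k]])
    class(out) <- c("pgl_rois", class(out))
    out
  })
}

#' Identify regions of interest for a gene set across donors
#'
#' For every donor, each region in the shared region universe (regions
#' sampled in at least `min_donors` donors) is tested with a two-sided
#' rank-sum enrichment test of the gene set against all other genes, with
#' Bonferroni correction for the universe size.  A region counts for a
#' donor when its adjusted p falls below `alpha` with a positive direction
#' (targets expressed above background).  Regions counting in at least
#' `min_freq` donors are returned, ranked by [rank_rois()].
#'
#' Genes in the set but absent from a donor are dropped for that donor.
#'
#' @param atlas A normalised `pgl_atlas` (see [normalize_within_donor()]).
#' @param gene_set A [gene_set()] or character vector; must intersect the
#'   atlas gene universe in at least 2 genes.
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @param min_freq Minimum number of counting donors for a region to be
#'   reported (default 5, the five-or-six-brains rule).
#' @param min_donors Region-universe rule: a region must be sampled in at
#'   least this many donors to be tested at all (default 5).
#' @return A `pgl_rois` tibble: `region`, `frequency`, `rank`,
#'   `effect_summary` (mean over counting donors of mean target z minus
#'   mean background z), `score` (mean -log10 adjusted p over counting
#'   donors), and a `per_donor` list-column of per-donor test details.
#'   Empty (zero rows) when no region reaches `min_freq`.
#' @export
get_rois <- function(atlas, gene_set, alpha = 0.05, min_freq = 5L,
                     min_donors = 5L) {
  get_rois_sets(atlas, list(gene_set), alpha = alpha, min_freq = min_freq,
                min_donors = min_donors)[[1]]
}

#' Rank regions of interest
#'
#' Orders ROIs by donor frequency (descending), then mean -log10 adjusted p
#' over counting donors (descending), then region identifier (ascending),
#' and assigns ranks 1..n without gaps.
#'
#' @param results Tibble with at least `region`, `frequency` and `score`
#'   columns (as produced inside [get_rois()]).
#' @return The same tibble, sorted, with a `rank` column.
#' @export
rank_rois <- function(results) {
  stopifnot(all(c("region", "frequency", "score") %in% names(results)))
  out <- results |>
    dplyr::arrange(dplyr::desc(.data$frequency), dplyr::desc(.data$score),
                   .data$region) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}
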