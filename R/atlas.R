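# Multi-donor expression atlas: data model, readers/writers, probe
# collapsing, within-donor normalisation, region universe rule.
#
# Internal layout: one numeric matrix per donor with genes in rows (the full
# union gene universe, NA where a gene was not measured in that donor) and
# sampled regions in columns.  Genes-in-rows makes per-gene z-scoring and
# per-region ranking cache-friendly at Allen-atlas scale (6 donors x ~250
# regions x ~20,000 genes).  On disk the conventional orientation (regions
# in rows, genes in columns) is used.

new_atlas <- function(exprs, normalized = FALSE, zero_variance = NULL) {
  stopifnot(is.list(exprs), length(exprs) >= 1, !is.null(names(exprs)))
  structure(
    list(
      donors = names(exprs),
      exprs = exprs,
      gene_universe = rownames(exprs[[1]]),
      normalized = normalized,
      zero_variance = zero_variance,
      cache = new.env(parent = emptyenv())
    ),
    class = "pgl_atlas"
  )
}

#' @export
print.pgl_atlas <- function(x, ...) {
  nreg <- vapply(x$exprs, ncol, integer(1))
  cat(sprintf("<pgl_atlas> %d donor(s), %d genes in universe, %s\n",
              length(x$donors), length(x$gene_universe),
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("regions per donor: %s\n",
              paste(sprintf("%s=%d", x$donors, nreg), collapse = ", ")))
  invisible(x)
}

# Align a list of gene x region matrices on the union gene universe; genes
# absent from a donor become NA rows (missing, never zero).
align_gene_universe <- function(mats) {
  universe <- sort(unique(unlist(lapply(mats, rownames))))
  lapply(mats, function(m) {
    out <- matrix(NA_real_, nrow = length(universe), ncol = ncol(m),
                  dimnames = list(universe, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
}

#' Assemble an expression atlas from per-donor matrices
#'
#' @param mats Named list (donor id -> matrix) of expression matrices with
#'   regions in rows and genes in columns (the on-disk orientation).
#' @return A `pgl_atlas` aligned on the union gene universe; genes absent
#'   from a donor are NA for that donor.
#' @export
as_atlas <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    names(mats) <- paste0("donor", seq_along(mats))
  }
  donor_ids <- names(mats)
  mats <- lapply(donor_ids, function(d) {
    m <- mats[[d]]
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort(sprintf("Donor '%s': matrix must carry region and gene names.", d))
    }
    if (anyDuplicated(rownames(m))) {
      abort(sprintf("Donor '%s': duplicate region identifier(s): %s", d,
                    paste(unique(rownames(m)[duplicated(rownames(m))]),
                          collapse = ", ")))
    }
    if (anyDuplicated(colnames(m))) {
      abort(sprintf("Donor '%s': duplicate gene column(s): %s", d,
                    paste(unique(colnames(m)[duplicated(colnames(m))]),
                          collapse = ", ")))
    }
    t(m)  # internal orientation: genes x regions
  })
  names(mats) <- donor_ids
  new_atlas(align_gene_universe(mats))
}

#' Read an expression atlas from per-donor delimited files
#'
#' Each file holds one donor's region-by-gene matrix: a header row of gene
#' symbols, a first column of region identifiers (hemisphere carried in the
#' name), tab- or comma-delimited.  Matrices are aligned on the union gene
#' universe; genes absent from a donor are marked missing, not zero.
#'
#' @param paths Character vector of file paths, named by donor id (unnamed
#'   paths are named after the file), or a single path to a YAML manifest
#'   with a `donors:` mapping of donor id to file path.
#' @return A `pgl_atlas`.
#' @export
read_atlas <- function(paths) {
  if (length(paths) == 1 && grepl("\\.ya?ml$", paths)) {
    manifest <- yaml::read_yaml(paths)
    if (is.null(manifest$donors)) {
      abort("Atlas manifest must contain a 'donors:' mapping.")
    }
    files <- unlist(manifest$donors)
    paths <- setNames(file.path(dirname(paths), files), names(files))
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    names(paths) <- sub("\\.[^.]+$", "", basename(paths))
  }
  mats <- lapply(names(paths), function(d) {
    path <- paths[[d]]
    if (!file.exists(path)) {
      abort(sprintf("Atlas file for donor '%s' not found: '%s'", d, path))
    }
    delim <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            progress = FALSE)
    regions <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- regions
    m
  })
  names(mats) <- names(paths)
  as_atlas(mats)
}

#' Write an expression atlas to per-donor TSV files
#'
#' Writes one `<donor>.tsv` per donor (regions in rows, genes in columns,
#' only the genes measured in that donor) plus a `manifest.yaml`.  The
#' numeric round trip through [read_atlas()] is exact.
#'
#' @param atlas A `pgl_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "pgl_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- setNames(paste0(atlas$donors, ".tsv"), atlas$donors)
  for (d in atlas$donors) {
    m <- atlas$exprs[[d]]
    m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]  # drop unmeasured genes
    df <- tibble::as_tibble(t(m), rownames = "region")
    readr::write_tsv(df, file.path(dir, files[[d]]), progress = FALSE)
  }
  yaml::write_yaml(list(donors = as.list(files),
                        normalized = atlas$normalized),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Collapse a probe-level matrix to gene level
#'
#' @param probe_matrix Numeric matrix with regions in rows and probes in
#'   columns.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   symbol (or a two-column data frame `probe`, `gene`).
#' @param method Summary across a gene's probes: `"mean"` (default,
#'   variance-stable) or `"max"`.
#' @return Region-by-gene numeric matrix.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene,
                            method = c("mean", "max")) {
  method <- match.arg(method)
  if (is.data.frame(probe_to_gene)) {
    probe_to_gene <- setNames(as.character(probe_to_gene[[2]]),
                              as.character(probe_to_gene[[1]]))
  }
  probes <- colnames(probe_matrix)
  unmapped <- setdiff(probes, names(probe_to_gene))
  if (length(unmapped) > 0) {
    abort(sprintf("Unmapped probe(s): %s", paste(unmapped, collapse = ", ")))
  }
  genes <- probe_to_gene[probes]
  fn <- if (method == "mean") rowMeans else function(m) apply(m, 1, max)
  groups <- split(seq_along(probes), genes)
  out <- matrix(NA_real_, nrow = nrow(probe_matrix), ncol = length(groups),
                dimnames = list(rownames(probe_matrix), names(groups)))
  for (g in names(groups)) {
    out[, g] <- fn(probe_matrix[, groups[[g]], drop = FALSE])
  }
  out
}

#' Z-score each gene across regions within each donor
#'
#' Per donor, every gene's expression profile across its sampled regions is
#' standardised to mean 0 and unit population (divide-by-n) standard
#' deviation.  Genes with zero variance (or fewer than two measured
#' regions) are set to all-zero and flagged; missing cells stay missing.
#' Idempotent up to numerical tolerance.
#'
#' @param atlas A raw `pgl_atlas` with at least two regions per donor.
#' @return A normalised `pgl_atlas`; the per-donor zero-variance gene lists
#'   are stored in its `zero_variance` field.
#' @export
normalize_within_donor <- function(atlas) {
  stopifnot(inherits(atlas, "pgl_atlas"))
  zero_var <- list()
  exprs <- lapply(atlas$donors, function(d) {
    m <- atlas$exprs[[d]]
    if (ncol(m) < 2) {
      abort(sprintf(
        "Donor '%s' has a single sampled region; cannot standardize.", d))
    }
    zs <- .row_zscore_cpp(m)
    zero_var[[d]] <<- rownames(m)[which(zs$degenerate)]
    zs$z
  })
  names(exprs) <- atlas$donors
  new_atlas(exprs, normalized = TRUE, zero_variance = zero_var)
}

#' Regions sampled in at least `min_donors` donors
#'
#' @param atlas A `pgl_atlas`.
#' @param min_donors Minimum number of donors in which a region must be
#'   sampled (default 5, the at-least-five-of-six rule).
#' @return Tibble with columns `region` and `n_donors`, sorted by region
#'   identifier.
#' @export
region_universe <- function(atlas, min_donors = 5L) {
  stopifnot(inherits(atlas, "pgl_atlas"))
  if (!is_number(min_donors) || min_donors < 1 ||
      min_donors > length(atlas$donors)) {
    abort("`min_donors` must be between 1 and the number of donors.")
  }
  counts <- table(unlist(lapply(atlas$exprs, colnames)))
  out <- tibble::tibble(region = names(counts),
                        n_donors = as.integer(counts)) |>
    dplyr::filter(.data$n_donors >= min_donors) |>
    dplyr::arrange(.data$region)
  if (nrow(out) == 0) {
    abort(sprintf(
      "No region is sampled in >= %d donors; lower `min_donors`.",
      as.integer(min_donors)))
  }
  out
}

# Per-donor rank matrices (ranks of genes within each region column) with
# tie bookkeeping; memoised on the atlas cache when precomputed.  The
# single-gene-set enrichment path uses the counting kernel instead (see
# donor_enrichment); the rank matrices pay off when many gene sets are
# evaluated against one atlas.
atlas_ranks <- function(atlas, donor) {
  key <- paste0("ranks_", donor)
  if (!is.null(atlas$cache[[key]])) return(atlas$cache[[key]])
  m <- atlas$exprs[[donor]]
  rk <- .col_ranks_cpp(m)
  dimnames(rk$ranks) <- dimnames(m)
  names(rk$n_obs) <- colnames(m)
  names(rk$tie_term) <- colnames(m)
  rk$s_all <- colSums(m, na.rm = TRUE)
  rk
}

#' Precompute per-donor rank matrices
#'
#' Ranks of genes within each region depend only on the atlas, never on the
#' gene set.  When many gene sets are evaluated against the same atlas
#' (split-half validation, random-list calibration), precomputing the rank
#' matrices once makes each subsequent [get_rois()] call nearly free.
#' Called automatically by [split_half_validation()] and
#' [false_positive_simulation()].
#'
#' @param atlas A normalised `pgl_atlas`.
#' @return The atlas, invisibly (rank matrices live on its cache).
#' @export
precompute_ranks <- function(atlas) {
  stopifnot(inherits(atlas, "pgl_atlas"))
  for (d in atlas$donors) {
    key <- paste0("ranks_", d)
    if (is.null(atlas$cache[[key]])) {
      atlas$cache[[key]] <- atlas_ranks(atlas, d)
    }
  }
  invisible(atlas)
}

has_rank_cache <- function(atlas) {
  all(vapply(paste0("ranks_", atlas$donors),
             function(k) !is.null(atlas$cache[[k]]), logical(1)))
}
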