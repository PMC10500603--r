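# Parsing TargetScan-style prediction tables and curating the conserved
# target set by Aggregate P_CT threshold.

#' Default column mapping for TargetScan-style summary tables
#'
#' TargetScan releases rename columns between versions, so the parser takes
#' an explicit mapping from logical field to column name.  The defaults
#' target the v8 "Summary Counts" layout.
#'
#' @param gene_symbol,mirna_family,aggregate_pct Column names in the file.
#' @return Named list used by [read_targetscan()].
#' @export
targetscan_cols <- function(gene_symbol = "Gene Symbol",
                            mirna_family = "miRNA family",
                            aggregate_pct = "Aggregate PCT") {
  list(gene_symbol = gene_symbol, mirna_family = mirna_family,
       aggregate_pct = aggregate_pct)
}

#' Read a TargetScan-style target-prediction table
#'
#' Parses a tab-separated prediction summary and keeps the rows whose miRNA
#' family matches `mirna_family`.  Rows with a missing or non-numeric
#' aggregate P_CT are skipped with a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param mirna_family Family label to keep (exact string match), e.g. the
#'   family containing miR-124-3p.
#' @param col_map Named list mapping the logical fields `gene_symbol`,
#'   `mirna_family` and `aggregate_pct` to column names in the file; see
#'   [targetscan_cols()].
#' @return Tibble with columns `gene_symbol`, `mirna_family`,
#'   `aggregate_pct` (one row per matching prediction, input order
#'   preserved).
#' @export
read_targetscan <- function(path, mirna_family, col_map = targetscan_cols()) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read TargetScan table: '%s' does not exist.", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  needed <- unlist(col_map[c("gene_symbol", "mirna_family", "aggregate_pct")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("TargetScan table is missing required column(s): %s",
                  paste0("'", missing_cols, "'", collapse = ", ")))
  }
  out <- tibble::tibble(
    gene_symbol = raw[[col_map$gene_symbol]],
    mirna_family = raw[[col_map$mirna_family]],
    aggregate_pct = suppressWarnings(as.numeric(raw[[col_map$aggregate_pct]]))
  )
  out <- out[out$mirna_family == mirna_family, , drop = FALSE]
  bad <- is.na(out$aggregate_pct)
  if (any(bad)) {
    warn(sprintf(
      "Skipping %d row(s) with missing/non-numeric aggregate P_CT (genes: %s).",
      sum(bad), paste(head(out$gene_symbol[bad], 5), collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  if (any(!is.na(out$aggregate_pct) &
          (out$aggregate_pct < 0 | out$aggregate_pct > 1))) {
    abort("Aggregate P_CT values must lie in [0, 1].")
  }
  if (any(!nzchar(out$gene_symbol))) {
    abort("Encountered an empty gene symbol.")
  }
  out
}

#' Construct a gene set
#'
#' A gene set is a tibble with a single `gene` column (unique, upper-cased
#' symbols, first-occurrence order) carrying a provenance record as an
#' attribute.
#'
#' @param genes Character vector of gene symbols.
#' @param provenance Named list describing where the set came from
#'   (source, miRNA family, threshold, ...).
#' @return A `pgl_gene_set` tibble.
#' @export
gene_set <- function(genes, provenance = list()) {
  genes <- toupper(as.character(genes))
  genes <- genes[!duplicated(genes)]
  out <- tibble::tibble(gene = genes)
  attr(out, "provenance") <- provenance
  class(out) <- c("pgl_gene_set", class(out))
  out
}

#' @export
print.pgl_gene_set <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<pgl_gene_set> %d genes\n", nrow(x)))
  if (length(prov) > 0) {
    cat("provenance:",
        paste(names(prov), unlist(lapply(prov, format)), sep = "=",
              collapse = ", "), "\n")
  }
  NextMethod()
}

#' Filter target predictions by aggregate P_CT
#'
#' Keeps genes whose aggregate P_CT is strictly greater than `threshold`
#' (the conserved-preferential-targeting rule), deduplicated keeping the
#' first occurrence, symbols upper-cased.
#'
#' @param records Tibble as returned by [read_targetscan()].
#' @param threshold Strict lower bound on aggregate P_CT, in `[0, 1)`.
#'   Defaults to 0.99.
#' @return A [gene_set()] whose provenance records the threshold.
#' @examples
#' recs <- tibble::tibble(gene_symbol = c("A", "B", "C"),
#'                        mirna_family = "miR-124-3p.1",
#'                        aggregate_pct = c(0.995, 0.50, 0.991))
#' filter_by_pct(recs)  # A and C
#' @export
filter_by_pct <- function(records, threshold = 0.99) {
  if (!is_number(threshold) || threshold < 0 || threshold >= 1) {
    abort("`threshold` must be a single number in [0, 1).")
  }
  stopifnot(all(c("gene_symbol", "aggregate_pct") %in% names(records)))
  keep <- !is.na(records$aggregate_pct) & records$aggregate_pct > threshold
  gene_set(
    records$gene_symbol[keep],
    provenance = list(
      threshold = threshold,
      rule = "aggregate_pct > threshold (strict)",
      mirna_family = if ("mirna_family" %in% names(records)) {
        paste(unique(records$mirna_family[keep]), collapse = ",")
      } else NA_character_,
      n_input_records = nrow(records)
    )
  )
}

#' Write / read a gene list with a YAML provenance sidecar
#'
#' `write_gene_set()` writes one gene symbol per line plus
#' `<path>.provenance.yaml`; `read_gene_set()` reads the pair back.
#'
#' @param x A [gene_set()].
#' @param path Output path for the plain-text gene list.
#' @return `write_gene_set()` returns `path` invisibly; `read_gene_set()`
#'   returns a [gene_set()].
#' @export
write_gene_set <- function(x, path) {
  stopifnot(inherits(x, "pgl_gene_set"))
  writeLines(x$gene, path)
  prov <- attr(x, "provenance") %||% list()
  yaml::write_yaml(prov, paste0(path, ".provenance.yaml"))
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  genes <- readLines(path)
  genes <- genes[nzchar(genes)]
  sidecar <- paste0(path, ".provenance.yaml")
  prov <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  gene_set(genes, provenance = prov)
}
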