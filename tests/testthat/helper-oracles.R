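# Independent oracles and small fixture builders.

# Brute-force two-sided Mann-Whitney p by enumeration of all group
# assignments of the pooled sample (valid with or without ties).
brute_force_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Small raw atlas built from explicit per-donor region x gene matrices.
toy_atlas <- function(..., donors = NULL) {
  mats <- list(...)
  names(mats) <- donors %||% paste0("d", seq_along(mats))
  as_atlas(mats)
}

# Region x gene matrix with named dims.
rg_matrix <- function(values, regions, genes) {
  matrix(values, nrow = length(regions), ncol = length(genes),
         dimnames = list(regions, genes), byrow = TRUE)
}

# Write a TargetScan-style TSV fixture; returns the path.
write_targetscan_fixture <- function(rows,
                                     header = c("Gene Symbol",
                                                "miRNA family",
                                                "Aggregate PCT")) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}
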