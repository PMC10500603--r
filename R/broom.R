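# Broom-style tidiers for pglr result objects.

#' Tidy a linear fit
#'
#' @param x A `pgl_fit` from [linear_fit()].
#' @param ... Unused.
#' @return One row per model term (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.pgl_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std.error = cf[, 2],
    statistic = cf[, 3],
    p.value = cf[, 4]
  )
}

#' @rdname tidy.pgl_fit
#' @export
glance.pgl_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, p.value = x$p, nobs = x$n)
}

#' Tidy an ROI result set
#'
#' Unnests the per-donor test details into one row per region and donor.
#'
#' @param x A `pgl_rois` from [get_rois()].
#' @param ... Unused.
#' @export
tidy.pgl_rois <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    tidyr::unnest("per_donor") |>
    dplyr::select("region", "frequency", "rank", "donor", "p", "adj_p",
                  "direction", "delta", "counts")
}

#' @rdname tidy.pgl_rois
#' @export
glance.pgl_rois <- function(x, ...) {
  tibble::tibble(
    n_rois = nrow(x),
    alpha = attr(x, "alpha"),
    min_freq = attr(x, "min_freq"),
    m_tests = attr(x, "m_tests"),
    n_donors = attr(x, "n_donors"),
    n_targets_in_universe = attr(x, "n_targets_in_universe")
  )
}

#' Tidy a match result
#'
#' @param x A `pgl_match` from [euclidean_match()].
#' @param ... Unused.
#' @return The pairs tibble (`case_id`, `control_id`, `distance`).
#' @export
tidy.pgl_match <- function(x, ...) x$pairs

#' @rdname tidy.pgl_match
#' @export
glance.pgl_match <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched = length(x$unmatched),
    total_distance = sum(x$pairs$distance),
    flagged_pre = sum(x$balance_pre$flagged, na.rm = TRUE),
    flagged_post = sum(x$balance_post$flagged, na.rm = TRUE)
  )
}

#' Tidy a correlation matrix
#'
#' @param x A `pgl_corr` from [correlation_matrix()].
#' @param ... Unused.
#' @return Long tibble of the lower triangle: `var1`, `var2`, `r`, `p`,
#'   `n`.
#' @export
tidy.pgl_corr <- function(x, ...) {
  vars <- colnames(x$r)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 2]],
    var2 = vars[idx[, 1]],
    r = x$r[idx],
    p = x$p[idx],
    n = x$n[idx]
  )
}
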