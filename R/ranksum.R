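# Wilcoxon rank-sum (Mann-Whitney) engine.
#
# One engine serves both the scalar two-sample comparison and the vectorised
# all-regions path of get_rois(): p-values are always computed from the
# Mann-Whitney U statistic plus group sizes and tie bookkeeping, so the two
# paths cannot drift apart.  Exact tail probabilities (stats::pwilcox) are
# used when both groups have <= 20 observations and there are no ties;
# otherwise the normal approximation with tie-corrected variance and
# continuity correction is used.  A fully tied sample yields p = 1.

RANKSUM_EXACT_MAX <- 20L

# Vectorised p-value from U and tie bookkeeping.  All arguments recycle to a
# common length.
ranksum_p <- function(U, n1, n2, N, tie_term, correct = TRUE) {
  k <- max(length(U), length(n1), length(n2), length(N), length(tie_term))
  U <- rep_len(U, k); n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  N <- rep_len(N, k); tie_term <- rep_len(tie_term, k)

  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  sigma2[N < 2] <- 0
  p <- rep(NA_real_, k)

  degenerate <- sigma2 <= 0 | n1 == 0 | n2 == 0
  p[degenerate] <- 1

  exact <- !degenerate & n1 <= RANKSUM_EXACT_MAX & n2 <= RANKSUM_EXACT_MAX &
    tie_term == 0
  if (any(exact)) {
    p[exact] <- mapply(function(u, a, b) {
      tail_p <- if (u > a * b / 2) {
        pwilcox(u - 1, a, b, lower.tail = FALSE)
      } else {
        pwilcox(u, a, b)
      }
      min(1, 2 * tail_p)
    }, U[exact], n1[exact], n2[exact])
  }

  approx <- !degenerate & !exact
  if (any(approx)) {
    z <- U[approx] - n1[approx] * n2[approx] / 2
    if (correct) z <- z - sign(z) * 0.5
    p[approx] <- pmin(1, 2 * pnorm(-abs(z) / sqrt(sigma2[approx])))
  }
  p
}

# Scalar engine: returns the rank sum W of x, U, p and the mean difference.
ranksum_engine <- function(x, y, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  tie_counts <- table(c(x, y))
  tie_term <- sum(tie_counts^3 - tie_counts)
  p <- ranksum_p(U, n1, n2, N, tie_term, correct = correct)
  delta <- mean(x) - mean(y)
  direction <- if (p == 1 && tie_term == N^3 - N) 0 else sign(delta)
  list(statistic = W, U = U, p = p, direction = direction, delta = delta,
       exact = n1 <= RANKSUM_EXACT_MAX && n2 <= RANKSUM_EXACT_MAX &&
         tie_term == 0,
       n_x = n1, n_y = n2)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney test: exact when both samples have at most 20
#' observations and no ties, otherwise a tie-corrected normal approximation
#' with continuity correction.  This is the same engine that drives the
#' per-region enrichment test in [get_rois()].
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @return A one-row tibble with `statistic` (rank sum of `x`), `p`,
#'   `method` (`"exact"` or `"normal-approx"`), and the sample sizes.
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
#' @export
rank_sum_compare <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x[!is.na(x)]) < 1 || length(y[!is.na(y)]) < 1) {
    abort("Both samples must contain at least one non-missing value.")
  }
  res <- ranksum_engine(x, y)
  tibble::tibble(
    statistic = res$statistic,
    p = res$p,
    method = if (res$exact) "exact" else "normal-approx",
    n_x = res$n_x,
    n_y = res$n_y
  )
}
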