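# Downstream volumetric and clinical statistics: ICV normalisation, group
# comparisons, regressions, correlation matrix, sensitivity re-runs, and
# the suicidal-ideation recovery score.

#' Normalise an ROI volume by intracranial volume
#'
#' Divides a region-of-interest volume (mm^3) by the participant's total
#' intracranial volume to remove head-size effects; the result is a
#' dimensionless ratio, invariant to common scaling.
#'
#' @param volume ROI volume(s), mm^3, `>= 0`.
#' @param icv Intracranial volume(s), mm^3, `> 0`.
#' @return `volume / icv`.
#' @export
icv_normalize <- function(volume, icv) {
  if (any(!is.finite(icv) | icv <= 0)) {
    abort("`icv` must be positive and finite.")
  }
  volume / icv
}

#' Unpaired t-test comparison
#'
#' Two-sided pooled-variance (default) or Welch unpaired t-test.  When both
#' samples are constant with equal means the comparison is degenerate and
#' p = 1 is returned by convention (with a note).
#'
#' @param x,y Numeric samples, each with at least 2 values.
#' @param welch Use the Welch (unequal variance) form?
#' @return One-row tibble: `statistic` (t), `df`, `p`, `method`, `n_x`,
#'   `n_y`, `note`.
#' @export
t_compare <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("Each sample needs at least 2 non-missing values.")
  }
  method <- if (welch) "Welch t-test" else "pooled t-test"
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    inform("Both samples constant with equal means; p = 1 by convention.")
    return(tibble::tibble(statistic = 0, df = NA_real_, p = 1,
                          method = method, n_x = length(x), n_y = length(y),
                          note = "degenerate: zero variance"))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, method = method,
                 n_x = length(x), n_y = length(y), note = NA_character_)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) by default, df = 1.
#'
#' @param table 2x2 matrix of non-negative counts (group x status).
#' @param correction Apply the Yates continuity correction?
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @examples
#' # counts reconstructed from printed prevalences of 22% vs 7% at n = 111
#' tab <- rbind(c(24, 87), c(8, 103))
#' chi_square_2x2(tab)  # p ~ 0.0022
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2.")
  if (any(table < 0) || any(!is.finite(table))) {
    abort("Counts must be finite and non-negative.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Both margins must be positive.")
  }
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  dev <- abs(table - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  tibble::tibble(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Simple linear regression of y on x
#'
#' Ordinary least squares via `stats::lm()`; `r_squared` is the squared
#' Pearson correlation and `p` the two-sided t-test on the slope.
#'
#' @param x,y Numeric vectors; pairwise-complete cases are used, `n >= 3`
#'   required, `x` must not be constant.
#' @return A `pgl_fit` object; see [tidy()] / [glance()] for tabular
#'   summaries, or its fields `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete (x, y) pairs.")
  if (sd(x) == 0) abort("`x` is constant; slope is undefined.")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
    n = length(x),
    fit = fit
  )
  class(out) <- "pgl_fit"
  out
}

#' @export
print.pgl_fit <- function(x, ...) {
  cat(sprintf(
    "<pgl_fit> slope %.4g, intercept %.4g, R^2 %.4g, p %.4g, n %d\n",
    x$slope, x$intercept, x$r_squared, x$p, x$n))
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t distribution; a variable with fewer than 3 complete pairs against all
#' others is flagged (its entries become NA), never silently dropped.
#'
#' @param data Data frame of numeric variables (at least 2 columns).
#' @return A `pgl_corr` list with matrices `r`, `p`, `n` and character
#'   vector `flagged`.
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  stopifnot(ncol(data) >= 2)
  vars <- names(data)
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) nmat[i, i] <- sum(!is.na(data[[i]]))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- complete.cases(data[[i]], data[[j]])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n >= 3) {
        rij <- stats::cor(data[[i]][ok], data[[j]][ok])
        r[i, j] <- r[j, i] <- rij
        if (abs(rij) < 1) {
          tstat <- rij * sqrt((n - 2) / (1 - rij^2))
          p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), n - 2)
        } else {
          p[i, j] <- p[j, i] <- 0
        }
      }
    }
  }
  offdiag_n <- nmat; diag(offdiag_n) <- NA
  flagged <- vars[apply(offdiag_n, 1, function(z) all(z < 3, na.rm = TRUE))]
  out <- list(r = r, p = p, n = nmat, flagged = flagged)
  class(out) <- "pgl_corr"
  out
}

#' @export
print.pgl_corr <- function(x, ...) {
  cat(sprintf("<pgl_corr> %d variables (pairwise-complete Pearson)\n",
              ncol(x$r)))
  print(round(x$r, 3))
  if (length(x$flagged) > 0) {
    cat("flagged (insufficient pairs):", paste(x$flagged, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Suicidal-ideation recovery score
#'
#' Defined as admission minus discharge ideation intensity, so that a
#' positive score means improvement over the inpatient stay.  Missing
#' either input propagates missing.
#'
#' @param admission,discharge Ideation intensity scores on a common scale.
#' @return `admission - discharge`.
#' @examples
#' delta_ideation(4, 1)  # 3 (improvement)
#' delta_ideation(1, 3)  # -2 (worsening)
#' @export
delta_ideation <- function(admission, discharge) {
  admission - discharge
}

#' Flag extreme upper values (Q3 + 3 IQR rule)
#'
#' Convenience predicate for sensitivity re-runs: values above the third
#' quartile plus three interquartile ranges are flagged.
#'
#' @param x Numeric vector.
#' @return Logical vector (NA values are never flagged).
#' @export
flag_outliers <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  !is.na(x) & x > q[2] + 3 * (q[2] - q[1])
}

#' Re-run an analysis after excluding participants
#'
#' Runs `analysis` on the full data and on the data with the exclusion
#' applied, reporting both results side by side together with the number
#' excluded — the pattern used for outlier-removal and age-subset
#' sensitivity checks.
#'
#' @param data Participant tibble.
#' @param analysis Function taking the (possibly filtered) tibble and
#'   returning a result (e.g. a one-row tibble of a test).
#' @param exclude Either a predicate function (row-wise on the tibble,
#'   returning a logical vector: `TRUE` = exclude) or a logical vector of
#'   length `nrow(data)`.
#' @return List: `before`, `after`, `n_excluded`.
#' @export
sensitivity_rerun <- function(data, analysis, exclude) {
  mask <- if (is.function(exclude)) exclude(data) else as.logical(exclude)
  if (length(mask) != nrow(data)) {
    abort("`exclude` must yield one logical per row.")
  }
  mask[is.na(mask)] <- FALSE
  before <- analysis(data)
  after <- tryCatch(
    analysis(data[!mask, , drop = FALSE]),
    error = function(e) abort(sprintf(
      "Analysis failed after excluding %d row(s): %s",
      sum(mask), conditionMessage(e)))
  )
  list(before = before, after = after, n_excluded = sum(mask))
}

#' Run the volumetric / clinical statistics battery on a cohort
#'
#' For a participant table with `case` and `control` groups: normalises the
#' focal ROI volume by ICV, compares it between groups with the rank-sum
#' test (confirmatory: only the top-ranked ROI is tested confirmatorily),
#' compares ideation scores with unpaired t-tests, compares age with a
#' Welch t-test, and fits the hypothesis-driven regressions (agreeableness,
#' neuroticism, age and recovery score against normalised volume) within
#' each group.
#'
#' @param participants Tibble with columns `group` (`case` / `control`),
#'   `age`, `icv`, the ROI volume column, BFI columns
#'   (`bfi_agreeableness`, `bfi_neuroticism`, ...) and ideation columns
#'   (`ideation_lifetime`, `ideation_admission`, `ideation_discharge`).
#' @param roi Name of the ROI volume column (default `"vol_roi"`).
#' @return Tidy tibble of every test: `analysis`, `group`, `label`
#'   (confirmatory / exploratory), `statistic`, `p`, `estimate`, `n`.
#' @export
cohort_stats <- function(participants, roi = "vol_roi") {
  stopifnot(all(c("group", "age", "icv", roi) %in% names(participants)))
  d <- participants |>
    dplyr::mutate(.ratio = icv_normalize(.data[[roi]], .data$icv))
  cases <- dplyr::filter(d, .data$group == "case")
  ctrls <- dplyr::filter(d, .data$group == "control")

  rows <- list()
  add <- function(analysis, group, label, statistic, p, estimate, n) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      analysis = analysis, group = group, label = label,
      statistic = statistic, p = p, estimate = estimate, n = n)
  }

  rs <- rank_sum_compare(cases$.ratio, ctrls$.ratio)
  add(paste0(roi, "/icv rank-sum case vs control"), "case-control",
      "confirmatory", rs$statistic, rs$p,
      mean(cases$.ratio, na.rm = TRUE) - mean(ctrls$.ratio, na.rm = TRUE),
      rs$n_x + rs$n_y)

  for (v in intersect(c("ideation_lifetime", "ideation_admission",
                        "ideation_discharge"), names(d))) {
    tt <- t_compare(cases[[v]], ctrls[[v]])
    add(paste0(v, " t-test case vs control"), "case-control", "exploratory",
        tt$statistic, tt$p, mean(cases[[v]], na.rm = TRUE) -
          mean(ctrls[[v]], na.rm = TRUE), tt$n_x + tt$n_y)
  }

  tt <- t_compare(cases$age, ctrls$age, welch = TRUE)
  add("age Welch t-test case vs control", "case-control", "exploratory",
      tt$statistic, tt$p,
      mean(cases$age, na.rm = TRUE) - mean(ctrls$age, na.rm = TRUE),
      tt$n_x + tt$n_y)

  reg_targets <- c(
    bfi_agreeableness = "confirmatory",
    bfi_neuroticism = "confirmatory",
    age = "exploratory",
    delta_ideation = "exploratory"
  )
  for (g in c("case", "control")) {
    gd <- if (g == "case") cases else ctrls
    if (all(c("ideation_admission", "ideation_discharge") %in% names(gd))) {
      gd$delta_ideation <- delta_ideation(gd$ideation_admission,
                                          gd$ideation_discharge)
    }
    for (v in intersect(names(reg_targets), names(gd))) {
      fit <- linear_fit(gd$.ratio, gd[[v]])
      add(paste0(v, " ~ ", roi, "/icv"), g,
          unname(reg_targets[[v]]), fit$slope, fit$p, fit$r_squared, fit$n)
    }
  }
  dplyr::bind_rows(rows)
}
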