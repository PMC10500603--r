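# Euclidean-distance case-control matching on demographics plus binary
# diagnosis flags, with balance diagnostics.

#' Matching feature scheme
#'
#' Declares which participant-table fields enter the Euclidean distance:
#' age (z-scored over the combined sample), sex and race (one-hot), and a
#' set of diagnosis columns, each contributing two binary coordinates
#' (past, current).
#'
#' @param age,sex,race Logical: include the field?
#' @param diagnoses Character vector of diagnosis column names (columns
#'   holding values in `absent` / `past` / `current`), or `NULL` to use
#'   every column starting with `dx_`.
#' @return A `pgl_match_scheme` list.
#' @export
match_scheme <- function(age = TRUE, sex = TRUE, race = TRUE,
                         diagnoses = NULL) {
  structure(list(age = age, sex = sex, race = race, diagnoses = diagnoses),
            class = "pgl_match_scheme")
}

scheme_diagnoses <- function(data, scheme) {
  scheme$diagnoses %||% grep("^dx_", names(data), value = TRUE)
}

#' Encode participants as numeric matching vectors
#'
#' One row per participant: age z-scored over the supplied table (so cases
#' and pool must be encoded together), sex and race one-hot over observed
#' levels, and per diagnosis two binary coordinates — past and current.
#'
#' @param data Participant tibble (the combined case + pool sample).
#' @param scheme A [match_scheme()].
#' @return Numeric matrix with `nrow(data)` rows, rownames = participant
#'   ids.
#' @export
encode_features <- function(data, scheme = match_scheme()) {
  stopifnot(inherits(scheme, "pgl_match_scheme"), is.data.frame(data))
  blocks <- list()
  need <- function(field) {
    if (!field %in% names(data)) {
      abort(sprintf("Matching scheme requires missing column '%s'.", field))
    }
    if (anyNA(data[[field]])) {
      bad <- data$id[is.na(data[[field]])]
      abort(sprintf("Participant(s) %s missing required field '%s'.",
                    paste(head(bad, 3), collapse = ", "), field))
    }
  }
  if (isTRUE(scheme$age)) {
    need("age")
    s <- sd(data$age)
    blocks$age <- if (s > 0) (data$age - mean(data$age)) / s
      else rep(0, nrow(data))
  }
  for (field in c("sex", "race")[c(isTRUE(scheme$sex), isTRUE(scheme$race))]) {
    need(field)
    lev <- sort(unique(as.character(data[[field]])))
    onehot <- vapply(lev, function(l) as.numeric(data[[field]] == l),
                     numeric(nrow(data)))
    colnames(onehot) <- paste0(field, "_", lev)
    blocks[[field]] <- onehot
  }
  for (dx in scheme_diagnoses(data, scheme)) {
    need(dx)
    v <- as.character(data[[dx]])
    bad <- setdiff(unique(v), c("absent", "past", "current"))
    if (length(bad) > 0) {
      abort(sprintf("Column '%s' has invalid diagnosis status: %s",
                    dx, paste(bad, collapse = ", ")))
    }
    m <- cbind(as.numeric(v == "past"), as.numeric(v == "current"))
    colnames(m) <- paste0(dx, c("_past", "_current"))
    blocks[[dx]] <- m
  }
  out <- do.call(cbind, blocks)
  out <- as.matrix(out)
  rownames(out) <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  out
}

#' Greedy Euclidean case-control matching
#'
#' Encodes cases and pool together with [encode_features()], then performs
#' greedy global matching without replacement: the minimum-distance
#' (case, control) pair among the unmatched is selected repeatedly, with a
#' deterministic tie-break by (case id, control id).  Balance diagnostics
#' ([balance_check()]) are reported before matching (cases vs whole pool)
#' and after (cases vs matched controls).
#'
#' @param cases,pool Participant tibbles with an `id` column and the
#'   scheme's fields.
#' @param scheme A [match_scheme()].
#' @return A `pgl_match` list: `pairs` tibble (`case_id`, `control_id`,
#'   `distance`), `unmatched` case ids, `balance_pre`, `balance_post`.
#' @export
euclidean_match <- function(cases, pool, scheme = match_scheme()) {
  if (nrow(pool) == 0) abort("Control pool is empty.")
  if (nrow(cases) == 0) abort("Case group is empty.")
  if (nrow(pool) < nrow(cases)) {
    warn(sprintf(
      "Pool (%d) smaller than cases (%d); matching will be partial.",
      nrow(pool), nrow(cases)))
  }
  combined <- dplyr::bind_rows(
    dplyr::mutate(cases, .role = "case"),
    dplyr::mutate(pool, .role = "pool")
  )
  X <- encode_features(combined, scheme)
  xc <- X[combined$.role == "case", , drop = FALSE]
  xp <- X[combined$.role == "pool", , drop = FALSE]

  # Full distance matrix, then one pass over pairs in (distance, ids) order.
  d2 <- outer(rowSums(xc^2), rowSums(xp^2), "+") - 2 * xc %*% t(xp)
  d2[d2 < 1e-10] <- 0  # cancellation noise; true distances are O(1) or 0
  d <- sqrt(d2)
  pair_idx <- expand.grid(case = seq_len(nrow(xc)), ctrl = seq_len(nrow(xp)))
  ord <- order(d[as.matrix(pair_idx)],
               rownames(xc)[pair_idx$case],
               rownames(xp)[pair_idx$ctrl])
  used_case <- logical(nrow(xc)); used_ctrl <- logical(nrow(xp))
  res_case <- integer(0); res_ctrl <- integer(0)
  for (k in ord) {
    i <- pair_idx$case[k]; j <- pair_idx$ctrl[k]
    if (!used_case[i] && !used_ctrl[j]) {
      used_case[i] <- TRUE; used_ctrl[j] <- TRUE
      res_case <- c(res_case, i); res_ctrl <- c(res_ctrl, j)
      if (all(used_case) || all(used_ctrl)) break
    }
  }
  pairs <- tibble::tibble(
    case_id = rownames(xc)[res_case],
    control_id = rownames(xp)[res_ctrl],
    distance = d[cbind(res_case, res_ctrl)]
  )
  unmatched <- rownames(xc)[!used_case]
  if (length(unmatched) > 0) {
    warn(sprintf("%d case(s) left unmatched.", length(unmatched)))
  }
  matched_pool <- pool[match(pairs$control_id, as.character(pool$id)), ,
                       drop = FALSE]
  vars <- c("age"[isTRUE(scheme$age)], "sex"[isTRUE(scheme$sex)],
            "race"[isTRUE(scheme$race)], scheme_diagnoses(combined, scheme))
  out <- list(
    pairs = pairs,
    unmatched = unmatched,
    balance_pre = balance_check(cases, pool, vars = vars),
    balance_post = balance_check(cases, matched_pool, vars = vars),
    scheme = scheme,
    algorithm = "greedy global minimum Euclidean distance, no replacement"
  )
  class(out) <- "pgl_match"
  out
}

#' @export
print.pgl_match <- function(x, ...) {
  cat(sprintf("<pgl_match> %d pair(s), %d unmatched; total distance %.4g\n",
              nrow(x$pairs), length(x$unmatched), sum(x$pairs$distance)))
  flagged <- sum(x$balance_post$flagged, na.rm = TRUE)
  cat(sprintf("post-match imbalanced variables (p < 0.05): %d (pre: %d)\n",
              flagged, sum(x$balance_pre$flagged, na.rm = TRUE)))
  invisible(x)
}

balance_one <- function(values, group) {
  if (is.numeric(values)) {
    if (sd(values) == 0) {
      return(tibble::tibble(test = "one-way ANOVA", statistic = NA_real_,
                            p = NA_real_,
                            note = "constant in all groups; skipped"))
    }
    fit <- aov(values ~ factor(group))
    tab <- suppressWarnings(anova(fit))
    tibble::tibble(test = "one-way ANOVA", statistic = tab$`F value`[1],
                   p = tab$`Pr(>F)`[1], note = NA_character_)
  } else {
    tab <- table(factor(group), factor(values))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || nrow(tab) < 2) {
      return(tibble::tibble(test = "chi-square", statistic = NA_real_,
                            p = NA_real_,
                            note = "constant in all groups; skipped"))
    }
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(test = "chi-square",
                   statistic = unname(cs$statistic), p = cs$p.value,
                   note = NA_character_)
  }
}

#' Post-match balance diagnostics
#'
#' One-way ANOVA on age across the supplied groups and uncorrected Pearson
#' chi-square tests for every categorical/diagnosis variable; a variable is
#' flagged imbalanced at p < 0.05 (no multiple-comparison correction).
#'
#' @param group_a,group_b Participant tibbles (two groups to compare).
#' @param group_c Optional third group.
#' @param vars Variables to test; defaults to `age`, `sex`, `race` and all
#'   `dx_` columns present.
#' @param alpha Flagging threshold (default 0.05).
#' @return Tibble: `variable`, `test`, `statistic`, `p`, `flagged`,
#'   `note`.
#' @export
balance_check <- function(group_a, group_b, group_c = NULL, vars = NULL,
                          alpha = 0.05) {
  groups <- list(group_a, group_b)
  if (!is.null(group_c)) groups <- c(groups, list(group_c))
  data <- dplyr::bind_rows(
    purrr::imap(groups, function(g, i) dplyr::mutate(g, .grp = i)))
  vars <- vars %||% intersect(
    c("age", "sex", "race", grep("^dx_", names(data), value = TRUE)),
    names(data))
  purrr::map_dfr(vars, function(v) {
    res <- balance_one(data[[v]], data$.grp)
    dplyr::mutate(res, variable = v, flagged = !is.na(res$p) & res$p < alpha,
                  .before = 1)
  })
}
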