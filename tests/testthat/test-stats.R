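test_that("ICV normalisation is a guarded scale-invariant ratio", {
  expect_equal(icv_normalize(1500, 1.5e6), 0.001)
  expect_equal(icv_normalize(0, 1.2e6), 0)
  expect_equal(icv_normalize(3000, 3e6), icv_normalize(1500, 1.5e6))
  expect_error(icv_normalize(100, 0), "positive")
  expect_error(icv_normalize(100, -5), "positive")
})

test_that("t comparisons cover pooled, Welch and degenerate cases", {
  r <- t_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  r2 <- t_compare(c(0, 0, 1, 1), c(10, 10, 11, 11))
  expect_lt(r2$p, 0.001)
  ref <- stats::t.test(c(0, 0, 1, 1), c(10, 10, 11, 11), var.equal = TRUE)
  expect_equal(r2$statistic, unname(ref$statistic))
  expect_equal(r2$p, ref$p.value)

  x <- c(1, 2, 3, 4, 10); y <- c(2.2, 2.4, 2.3, 2.5)
  pooled <- t_compare(x, y, welch = FALSE)
  welch <- t_compare(x, y, welch = TRUE)
  expect_false(isTRUE(all.equal(pooled$df, welch$df)))

  expect_message(deg <- t_compare(c(2, 2), c(2, 2)), "convention")
  expect_equal(deg$p, 1)
  expect_error(t_compare(1, c(1, 2)), "at least 2")
})

test_that("uncorrected 2x2 chi-square matches chisq.test and the z-test identity", {
  tab <- rbind(c(24, 87), c(8, 103))
  ours <- chi_square_2x2(tab)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  withc <- chi_square_2x2(tab, correction = TRUE)
  refc <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(withc$p, refc$p.value, tolerance = 1e-12)

  # chi2 with df = 1 is the squared two-proportion z statistic
  expect_equal(ours$p, 2 * pnorm(-sqrt(ours$chi2)), tolerance = 1e-12)

  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margins")
  expect_error(chi_square_2x2(matrix(1:6, 2)), "2x2")
})

test_that("linear fits recover exact and degenerate relationships", {
  x <- c(0, 1, 2, 3)
  fit <- suppressWarnings(linear_fit(x, 2 * x + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- linear_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0, tolerance = 1e-12)

  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(linear_fit(c(1, 2), c(1, 2)), "at least 3")

  set.seed(14)
  x <- rnorm(111); y <- 3 + 0.5 * x + rnorm(111)
  fit2 <- linear_fit(x, y)
  se <- tidy(fit2)$std.error[2]
  expect_lt(abs(fit2$slope - 0.5), 3 * se)
  g <- glance(fit2)
  expect_equal(g$slope, fit2$slope)
  expect_equal(g$nobs, 111)
})

test_that("correlation matrices are symmetric with pairwise handling", {
  d <- tibble::tibble(
    a = c(1, -1, 1, -1),
    b = c(1, 1, -1, -1),
    c = c(1, 2, 3, 4)
  )
  cm <- correlation_matrix(d)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], 0, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$p, t(cm$p))

  d2 <- tibble::tibble(a = c(1, 2, NA, 4, 5), b = c(2, 4, 6, NA, 10),
                       c = c(NA, NA, NA, 1, 2))
  cm2 <- correlation_matrix(d2)
  expect_equal(cm2$n["a", "b"], 3)
  expect_true("c" %in% cm2$flagged)  # < 3 complete pairs everywhere
  tl <- tidy(cm2)
  expect_equal(nrow(tl), 3)
})

test_that("the recovery score is admission minus discharge", {
  expect_equal(delta_ideation(4, 1), 3)
  expect_equal(delta_ideation(2, 2), 0)
  expect_equal(delta_ideation(1, 3), -2)
  expect_true(is.na(delta_ideation(NA, 3)))
})

test_that("sensitivity re-runs report before/after and exclusion counts", {
  set.seed(30)
  cohort <- tibble::tibble(
    id = sprintf("s%03d", 1:60),
    age = c(rnorm(46, 30, 4), rnorm(14, 50, 3)),
    score = rnorm(60)
  )
  count_n <- function(d) nrow(d)
  none <- sensitivity_rerun(cohort, count_n, exclude = rep(FALSE, 60))
  expect_equal(none$before, none$after)
  expect_equal(none$n_excluded, 0)

  older <- sensitivity_rerun(cohort, count_n,
                             exclude = function(d) d$age > 40)
  expect_equal(older$n_excluded, 14)
  expect_equal(older$after, 46)

  # an extreme value that drives a rank-sum separation: excluding it moves
  # the p-value toward 1
  two_group <- tibble::tibble(
    group = rep(c("x", "y"), each = 6),
    value = c(1.02, 1.18, 1.12, 1.08, 1.21, 9.0,
              1.05, 1.15, 1.10, 1.20, 1.13, 1.17)
  )
  pfun <- function(d) {
    rank_sum_compare(d$value[d$group == "x"], d$value[d$group == "y"])$p
  }
  sens <- sensitivity_rerun(two_group, pfun,
                            exclude = function(d) flag_outliers(d$value))
  expect_equal(sens$n_excluded, 1)
  expect_gt(sens$after, sens$before)

  expect_error(sensitivity_rerun(two_group, pfun, exclude = TRUE),
               "one logical per row")
})

test_that("outlier flagging applies the Q3 + 3 IQR rule", {
  x <- c(rep(1:5, 4), 100)
  expect_equal(which(flag_outliers(x)), 21)
  expect_false(any(flag_outliers(c(x[-21], NA))[21]))
})

test_that("the cohort battery labels confirmatory and exploratory analyses", {
  coh <- make_cohort(synthetic_cohort_config(n_per_group = 60, seed = 8))
  out <- cohort_stats(coh)
  expect_true(all(c("analysis", "group", "label", "statistic", "p", "n")
                  %in% names(out)))
  conf <- out[out$label == "confirmatory", ]
  expect_true(any(grepl("rank-sum", conf$analysis)))
  expect_true(all(out$p >= 0 & out$p <= 1, na.rm = TRUE))
  # volume deficit is detectable even at n = 60
  expect_lt(out$p[grepl("rank-sum", out$analysis)], 0.01)
})
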