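mini_participants <- function(ids, age, sex, dx_current) {
  tibble::tibble(
    id = ids,
    age = age,
    sex = sex,
    race = "white",
    dx_mood = ifelse(dx_current, "current", "absent")
  )
}

test_that("feature encoding follows the scheme contract", {
  d <- mini_participants(c("a", "b"), c(30, 30), c("f", "f"), c(TRUE, TRUE))
  X <- encode_features(d, match_scheme())
  expect_equal(nrow(X), 2)
  expect_equal(unname(X[1, ]), unname(X[2, ]))  # identical -> distance 0

  # one current diagnosis apart -> squared distance exactly 1
  d2 <- mini_participants(c("a", "b"), c(30, 30), c("f", "f"),
                          c(TRUE, FALSE))
  X2 <- encode_features(d2, match_scheme())
  expect_equal(sum((X2[1, ] - X2[2, ])^2), 1)

  # scheme without age drops the age coordinate
  X3 <- encode_features(d2, match_scheme(age = FALSE))
  expect_equal(ncol(X3), ncol(X2) - 1)
  expect_false("age" %in% colnames(X3))

  d3 <- d2; d3$age[2] <- NA
  expect_error(encode_features(d3, match_scheme()), "missing required")
  expect_error(encode_features(dplyr::select(d2, -"sex"), match_scheme()),
               "'sex'")
})

test_that("greedy matching picks nearest controls without replacement", {
  cases <- mini_participants("c1", 30, "f", TRUE)
  pool <- mini_participants(c("p1", "p2"), c(50, 31), c("f", "f"),
                            c(TRUE, TRUE))
  m <- euclidean_match(cases, pool)
  expect_equal(m$pairs$control_id, "p2")

  # exact duplicate in the pool is matched at distance zero
  pool2 <- mini_participants(c("p1", "p2"), c(50, 30), c("m", "f"),
                             c(FALSE, TRUE))
  m2 <- euclidean_match(cases, pool2)
  expect_equal(m2$pairs$control_id, "p2")
  expect_equal(m2$pairs$distance, 0)

  # partial matching warns and reports the unmatched case
  cases3 <- mini_participants(c("c1", "c2"), c(30, 40), c("f", "m"),
                              c(TRUE, FALSE))
  pool3 <- mini_participants("p1", 30, "f", TRUE)
  expect_warning(expect_warning(m3 <- euclidean_match(cases3, pool3),
                              "smaller"), "unmatched")
  expect_equal(nrow(m3$pairs), 1)
  expect_equal(m3$unmatched, "c2")

  expect_error(euclidean_match(cases, pool[0, ]), "empty")
})

test_that("matching identical populations gives zero total distance", {
  set.seed(4)
  cases <- tibble::tibble(
    id = sprintf("c%02d", 1:20),
    age = rnorm(20, 30, 5),
    sex = sample(c("f", "m"), 20, TRUE),
    race = sample(c("w", "b"), 20, TRUE),
    dx_mood = sample(c("absent", "past", "current"), 20, TRUE)
  )
  pool <- dplyr::mutate(cases, id = sprintf("p%02d", 1:20))
  m <- euclidean_match(cases, pool)
  expect_equal(nrow(m$pairs), 20)
  expect_equal(sum(m$pairs$distance), 0)
  expect_equal(anyDuplicated(m$pairs$control_id), 0)
})

test_that("balance diagnostics use ANOVA for age and chi-square otherwise", {
  g1 <- mini_participants(sprintf("a%d", 1:3), c(20, 21, 22),
                          c("f", "f", "m"), c(TRUE, FALSE, FALSE))
  g2 <- mini_participants(sprintf("b%d", 1:3), c(30, 31, 32),
                          c("f", "f", "m"), c(TRUE, FALSE, FALSE))
  b <- balance_check(g1, g2)
  age_row <- b[b$variable == "age", ]
  expect_equal(age_row$test, "one-way ANOVA")
  expect_lt(age_row$p, 0.01)
  expect_true(age_row$flagged)
  # race constant in both groups: skipped with a note
  race_row <- b[b$variable == "race", ]
  expect_true(is.na(race_row$p))
  expect_match(race_row$note, "skipped")

  # identical groups: nothing flagged
  b2 <- balance_check(g1, dplyr::mutate(g1, id = paste0(id, "x")))
  expect_false(any(b2$flagged, na.rm = TRUE))
})

test_that("published prevalence contrast reproduces its chi-square p", {
  status_a <- rep(c("current", "absent"), c(24, 87))
  status_b <- rep(c("current", "absent"), c(8, 103))
  g1 <- tibble::tibble(id = sprintf("a%03d", 1:111), dx_ocd = status_a)
  g2 <- tibble::tibble(id = sprintf("b%03d", 1:111), dx_ocd = status_b)
  b <- balance_check(g1, g2, vars = "dx_ocd")
  expect_equal(b$p, 0.0022, tolerance = 1e-2)
  expect_equal(round(b$p, 4), 0.0022)
})

test_that("matching a shifted pool improves covariate balance", {
  d <- make_match_pool(n_cases = 80, pool_size = 240, seed = 11)
  cases <- d[d$group == "case", ]
  pool <- d[d$group == "pool", ]
  m <- euclidean_match(cases, pool)
  expect_equal(nrow(m$pairs), 80)
  expect_lt(sum(m$balance_post$flagged, na.rm = TRUE),
            sum(m$balance_pre$flagged, na.rm = TRUE))
  g <- glance(m)
  expect_equal(g$n_pairs, 80)
  expect_equal(g$flagged_post, sum(m$balance_post$flagged, na.rm = TRUE))
})
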