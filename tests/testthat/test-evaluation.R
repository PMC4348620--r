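test_that("empirical AUC equals the pairwise-counting oracle and pROC", {
  skip_if_not_installed("pROC")
  for (i in 1:10) {
    withr::with_seed(600 + i, {
      n <- sample(10:40, 1)
      y <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
      s <- round(rnorm(n), 1)   # coarse scores force some ties
    })
    d <- tibble::tibble(score = s, recurrence = y)
    auc <- roc_auc_smoothed(d)$auc_empirical
    expect_equal(auc, u_statistic(s[y], s[!y]) / (sum(y) * sum(!y)))
    expect_equal(auc,
                 as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))))
  }
})

test_that("perfect separation and label noise hit the AUC extremes", {
  d <- tibble::tibble(score = c(1:5, 6:10),
                      recurrence = rep(c(FALSE, TRUE), each = 5))
  expect_equal(roc_auc_smoothed(d)$auc_empirical, 1.0)
  withr::with_seed(2, {
    big <- tibble::tibble(score = rnorm(2000),
                          recurrence = sample(c(TRUE, FALSE), 2000, TRUE))
  })
  expect_lt(abs(roc_auc_smoothed(big)$auc_empirical - 0.5), 0.05)
  expect_error(roc_auc_smoothed(tibble::tibble(score = 1:3,
                                               recurrence = rep(TRUE, 3))),
               "both classes")
})

test_that("binormal smoothing matches its closed form", {
  withr::with_seed(3, {
    d <- tibble::tibble(
      score = c(rnorm(2000, 0, 1), rnorm(2000, 1, 1)),
      recurrence = rep(c(FALSE, TRUE), each = 2000))
  })
  r <- roc_auc_smoothed(d)
  truth <- pnorm(1 / sqrt(2))
  # Hanley-McNeil SE at this n is ~0.007
  se <- sqrt(truth * (1 - truth) / 2000) * 2
  expect_lt(abs(r$auc_smoothed - truth), 3 * se)
})

test_that("bootstrap CI is seeded, ordered, and covers the point estimate", {
  withr::with_seed(4, {
    d <- tibble::tibble(score = c(rnorm(40), rnorm(40, 1.2)),
                        recurrence = rep(c(FALSE, TRUE), each = 40))
  })
  ci1 <- bootstrap_auc_ci(d, reps = 300, seed = 11)
  ci2 <- bootstrap_auc_ci(d, reps = 300, seed = 11)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, ci1$upper)
  expect_true(ci1$lower <= ci1$estimate && ci1$estimate <= ci1$upper)
  # CI narrows with sample size
  withr::with_seed(5, {
    big <- tibble::tibble(score = c(rnorm(160), rnorm(160, 1.2)),
                          recurrence = rep(c(FALSE, TRUE), each = 160))
  })
  ci3 <- bootstrap_auc_ci(big, reps = 300, seed = 11)
  expect_lt(ci3$upper - ci3$lower, ci1$upper - ci1$lower)
})

test_that("paired AUC-difference bootstrap behaves at the extremes", {
  withr::with_seed(6, {
    d <- tibble::tibble(good = c(rnorm(50), rnorm(50, 3)),
                        noise = rnorm(100),
                        recurrence = rep(c(FALSE, TRUE), each = 50))
  })
  same <- bootstrap_auc_difference(
    dplyr::mutate(d, copy = good), "good", "copy", reps = 200, seed = 7)
  expect_equal(same$p_value, 1)
  diff <- bootstrap_auc_difference(d, "good", "noise", reps = 500, seed = 8)
  expect_lt(diff$p_value, 0.01)
  r1 <- bootstrap_auc_difference(d, "good", "noise", reps = 200, seed = 9)
  r2 <- bootstrap_auc_difference(d, "good", "noise", reps = 200, seed = 9)
  expect_identical(r1, r2)
})

test_that("KS comparison agrees with an ECDF max-gap oracle", {
  same <- tibble::tibble(score = rep(1:5, 2),
                         recurrence = rep(c(TRUE, FALSE), each = 5))
  expect_equal(ks_compare(same)$statistic, 0)
  disjoint <- tibble::tibble(score = c(1:5, 11:15),
                             recurrence = rep(c(TRUE, FALSE), each = 5))
  expect_equal(ks_compare(disjoint)$statistic, 1)
  for (i in 1:5) {
    withr::with_seed(700 + i, {
      x <- rnorm(30); y <- rnorm(25, 0.5)
    })
    d <- tibble::tibble(score = c(x, y),
                        recurrence = rep(c(TRUE, FALSE), c(30, 25)))
    expect_equal(ks_compare(d)$statistic, ks_d_oracle(x, y))
  }
})

test_that("binomial tail p-values match the closed forms", {
  expect_equal(binom.test(8, 10, 0.5, "greater")$p.value, 56 / 1024)
  expect_equal(binom.test(12, 12, 0.5, "greater")$p.value, 0.5^12)
})

test_that("quartile odds ratios match the contingency-table oracle", {
  # 48 patients; scores order them into quartiles of 12 with known case mix
  cases_per_q <- c(2, 4, 6, 10)
  y <- unlist(lapply(cases_per_q, function(k) rep(c(TRUE, FALSE), c(k, 12 - k))))
  d <- tibble::tibble(score = seq_len(48) / 48, recurrence = y)
  out <- quartile_odds_ratios(d)
  expect_equal(out$quartile, 1:4)
  expect_equal(out$n, rep(12L, 4))
  expect_equal(out$cases, cases_per_q)
  or_oracle <- function(k) (k / (12 - k)) / (2 / 10)
  expect_equal(out$odds_ratio, c(1, or_oracle(4), or_oracle(6), or_oracle(10)),
               tolerance = 1e-5)
  expect_lt(glance(out)$p_trend, 0.05)
})

test_that("quartile sizes differ by at most one and nulls cover OR = 1", {
  withr::with_seed(8, {
    d <- tibble::tibble(score = rnorm(50),
                        recurrence = sample(c(TRUE, FALSE), 50, TRUE, c(.4, .6)))
  })
  out <- quartile_odds_ratios(d)
  expect_lte(diff(range(out$n)), 1)
  covered <- vapply(2:4, function(k) {
    row <- out[out$quartile == k, ]
    row$ci_lower <= 1 && 1 <= row$ci_upper
  }, logical(1))
  expect_gte(sum(covered), 2)
})
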