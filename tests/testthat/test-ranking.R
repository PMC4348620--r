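ranking_fixture <- function(n_pairs = 10, gap = 1, sd = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- 4 * n_pairs
    tibble::tibble(
      core_id = sprintf("c%03d", seq_len(n)),
      patient_id = rep(sprintf("P%03d", seq_len(2 * n_pairs)), each = 2),
      pair_id = rep(sprintf("PR%02d", seq_len(n_pairs)), each = 4),
      recurrence = rep(rep(c(TRUE, FALSE), each = 2), n_pairs),
      f1 = ifelse(rep(rep(c(TRUE, FALSE), each = 2), n_pairs),
                  gap, 0) + rnorm(n, 0, sd))
  })
}

test_that("a separable one-feature problem trains to perfect pairwise accuracy", {
  d <- ranking_fixture(gap = 1, sd = 0)
  d$f1 <- d$f1 + seq(0, 0.1, length.out = nrow(d))   # break exact ties
  model <- train_ranking_svm(d, features = "f1")
  expect_equal(model$training_accuracy, 1.0)
  expect_gt(model$weights[["f1"]], 0)
})

test_that("identical features raise a degenerate-model error", {
  d <- ranking_fixture(gap = 0, sd = 0)
  expect_error(train_ranking_svm(d, features = "f1"), "degenerate")
})

test_that("shuffled labels give chance-level held-out pairwise accuracy", {
  accs <- vapply(1:6, function(s) {
    tr <- ranking_fixture(n_pairs = 24, gap = 0, sd = 1, seed = s)
    model <- train_ranking_svm(tr[tr$pair_id <= "PR16", ], features = "f1")
    te <- tr[tr$pair_id > "PR16", ]
    sc <- predict(model, te)
    cases <- sc[te$recurrence]; ctrls <- sc[!te$recurrence]
    mean(outer(cases, ctrls, ">"))
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("rescaling features does not change the induced ordering", {
  d <- ranking_fixture(n_pairs = 12, gap = 0.5, sd = 0.4, seed = 3)
  d$f2 <- withr::with_seed(4, rnorm(nrow(d)))
  m1 <- train_ranking_svm(d, features = c("f1", "f2"))
  d2 <- d; d2$f1 <- d2$f1 * 10; d2$f2 <- d2$f2 * 0.01
  m2 <- train_ranking_svm(d2, features = c("f1", "f2"))
  expect_equal(order(predict(m1, d)), order(predict(m2, d2)))
})

test_that("rank_samples assigns 1..N with stable tie handling", {
  d <- ranking_fixture(n_pairs = 2, gap = 1)
  model <- train_ranking_svm(
    dplyr::mutate(d, f1 = f1 + seq(0, 0.2, length.out = nrow(d))),
    features = "f1")
  scored <- tibble::tibble(f1 = c(0.2, 0.9, 0.5))
  out <- rank_samples(model, scored)
  expect_equal(out$rank, c(1L, 3L, 2L))
  tied <- tibble::tibble(f1 = c(0.5, 0.5, 0.1))
  expect_warning(rt <- rank_samples(model, tied), "tie")
  expect_equal(rt$rank, c(2L, 3L, 1L))   # stable: first tied input ranks lower
})

test_that("preference score matches the worked extremes", {
  # S1 holds the top two of four pooled ranks
  p <- preference_score(c(3, 4), c(1, 2))
  expect_equal(p$preference, 7)
  expect_equal(p$pref_min, 3)
  expect_equal(p$pref_max, 7)
  expect_equal(p$npreference, 1)
  expect_equal(preference_score(c(1, 2), c(3, 4))$npreference, 0)
  expect_error(preference_score(numeric(0), 1), "non-empty")
  expect_error(preference_score(1, 2, d = 0.5), "d")
})

test_that("nPreference equals the normalized Mann-Whitney U at d = 1", {
  for (i in 1:40) {
    withr::with_seed(400 + i, {
      n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
      s1 <- runif(n1); s2 <- runif(n2)
    })
    np <- npreference(s1, s2)
    expect_equal(np, u_statistic(s1, s2) / (n1 * n2))
    # symmetry without ties
    expect_equal(np + npreference(s2, s1), 1)
  }
})

test_that("balanced nesting of equal-size sets gives nPreference one half", {
  expect_equal(npreference(c(1, 4), c(2, 3)), 0.5)
  expect_equal(npreference(c(2, 3), c(1, 4)), 0.5)
  expect_equal(npreference(c(1, 4, 5, 8), c(2, 3, 6, 7)), 0.5)
})

test_that("tidy and glance summarize a ranking model", {
  d <- ranking_fixture(n_pairs = 6, gap = 1, sd = 0.2, seed = 9)
  m <- train_ranking_svm(d, features = "f1")
  td <- tidy(m)
  expect_equal(td$term, "f1")
  gl <- glance(m)
  expect_equal(gl$n_features, 1L)
  expect_true(gl$training_accuracy >= 0 && gl$training_accuracy <= 1)
})
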