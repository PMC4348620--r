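# build a per-core feature table with known informative features
feature_fixture <- function(n_pairs = 12, n_noise = 8, seed = 1, sd = 0.05) {
  withr::with_seed(seed, {
    n <- 4 * n_pairs   # two cores per patient
    pair <- rep(sprintf("PR%02d", seq_len(n_pairs)), each = 4)
    patient <- rep(sprintf("P%03d", seq_len(2 * n_pairs)), each = 2)
    recurrence <- rep(rep(c(TRUE, FALSE), each = 2), n_pairs)
    d <- tibble::tibble(core_id = sprintf("c%03d", seq_len(n)),
                        patient_id = patient, pair_id = pair,
                        recurrence = recurrence)
    d$inf_1 <- ifelse(recurrence, 0.30, 0.10) + rnorm(n, 0, sd)
    d$inf_2 <- ifelse(recurrence, 0.25, 0.08) + rnorm(n, 0, sd)
    for (j in seq_len(n_noise)) d[[sprintf("noise_%d", j)]] <- runif(n, 0, 0.3)
    d
  })
}

test_that("a perfectly separating feature is selected first", {
  d <- feature_fixture(seed = 2, sd = 0.01)
  out <- rank_relevance_redundancy(d, k0 = 3)
  expect_equal(out$feature[1], "inf_1")
  expect_equal(out$step, 1:3)
})

test_that("a duplicated feature is penalized for redundancy", {
  d <- feature_fixture(seed = 3, sd = 0.02)
  d$dup <- d$inf_1                     # exact copy of the top feature
  out <- rank_relevance_redundancy(d, k0 = 3)
  expect_equal(out$feature[1], "inf_1")
  # the copy must not be chosen before the other informative feature
  expect_lt(match("inf_2", out$feature), match("dup", c(out$feature, "dup")))
})

test_that("greedy ordering equals brute-force evaluation of the criterion", {
  d <- feature_fixture(n_pairs = 8, n_noise = 3, seed = 4)
  feats <- c("inf_1", "inf_2", "noise_1", "noise_2", "noise_3")
  out <- rank_relevance_redundancy(d[, c("recurrence", feats)], k0 = 5)
  # independent re-implementation of the greedy criterion
  bin10 <- function(x) {
    qs <- unique(quantile(x, seq(0, 1, 0.1), names = FALSE))
    if (length(qs) < 2) rep(1L, length(x)) else
      cut(x, qs, include.lowest = TRUE, labels = FALSE)
  }
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb))
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    s
  }
  xb <- lapply(d[, feats], bin10)
  y <- d$recurrence
  rel <- vapply(xb, mi, numeric(1), b = y)
  sel <- character(0); rem <- feats
  for (step in 1:5) {
    crit <- vapply(rem, function(f) {
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s) mi(xb[[f]], xb[[s]]), numeric(1)))
      rel[[f]] - red
    }, numeric(1))
    best <- rem[which.max(crit)]
    sel <- c(sel, best); rem <- setdiff(rem, best)
  }
  expect_equal(out$feature, sel)
})

test_that("k0 larger than the pool returns everything with a warning", {
  d <- feature_fixture(n_pairs = 6, n_noise = 2, seed = 5)
  expect_warning(out <- rank_relevance_redundancy(d, k0 = 50), "exceeds")
  expect_equal(nrow(out), 4)
})

test_that("refinement accepts only strict improvements", {
  d <- feature_fixture(seed = 6, sd = 0.02)
  ref <- refine_subset(d, initial = "inf_1", folds = 3, max_iter = 2, seed = 1)
  expect_true(all(diff(ref$trace) > 0))
  expect_equal(ref$objective, max(ref$trace))
  expect_gte(ref$objective, ref$trace[1])
  expect_true("inf_1" %in% ref$selected)
})

test_that("refinement recovers a complementary informative pair in most seeds", {
  # inf_1 separates the odd pairs only, inf_2 the even pairs only, so one
  # feature alone tops out near 75% pairwise accuracy and the pair is
  # needed to approach 100%
  complementary_fixture <- function(n_pairs = 10, seed = 1) {
    withr::with_seed(seed, {
      n <- 4 * n_pairs
      pair_num <- rep(seq_len(n_pairs), each = 4)
      d <- tibble::tibble(
        core_id = sprintf("c%03d", seq_len(n)),
        patient_id = rep(sprintf("P%03d", seq_len(2 * n_pairs)), each = 2),
        pair_id = sprintf("PR%02d", pair_num),
        recurrence = rep(rep(c(TRUE, FALSE), each = 2), n_pairs))
      odd <- pair_num %% 2 == 1
      d$inf_1 <- 0.1 + 0.25 * (d$recurrence & odd) + rnorm(n, 0, 0.03)
      d$inf_2 <- 0.1 + 0.25 * (d$recurrence & !odd) + rnorm(n, 0, 0.03)
      for (j in 1:4) d[[sprintf("noise_%d", j)]] <- runif(n, 0, 0.3)
      d
    })
  }
  hits <- 0
  for (s in 1:10) {
    d <- complementary_fixture(seed = 100 + s)
    ref <- refine_subset(d, initial = "inf_1", folds = 3, max_iter = 2,
                         seed = s)
    if (all(c("inf_1", "inf_2") %in% ref$selected)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
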