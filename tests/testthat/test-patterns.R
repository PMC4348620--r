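test_that("mining reproduces the worked four-pixel example", {
  m <- matrix(c(0L, 0L,
                0L, 0L,
                0L, 1L,
                1L, 1L), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("metric_1", "metric_2")))
  out <- mine_frequent_patterns(m, theta = 0.5)
  expect_setequal(out$pattern_id, c("m1=0", "m2=0", "m2=1", "m1=0|m2=0"))
  expect_equal(out$support[out$pattern_id == "m1=0"], 0.75)
  expect_equal(out$support[out$pattern_id == "m1=0|m2=0"], 0.5)
})

test_that("theta = 1 on identical rows returns the full itemset lattice", {
  m <- matrix(rep(c(2L, 0L, 1L), each = 5), ncol = 3,
              dimnames = list(NULL, sprintf("metric_%d", 1:3)))
  out <- mine_frequent_patterns(m, theta = 1)
  expect_equal(nrow(out), 7)           # all non-empty subsets of 3 items
  expect_true(all(out$support == 1))
  m2 <- matrix(c(0L, 0L, 1L, 1L), ncol = 1,
               dimnames = list(NULL, "metric_1"))
  expect_equal(nrow(mine_frequent_patterns(m2, theta = 0.6)), 0)
})

test_that("FP-growth equals exhaustive enumeration on random instances", {
  for (i in 1:12) {
    withr::with_seed(100 + i, {
      n <- sample(20:120, 1); k <- sample(2:5, 1)
      m <- matrix(sample(0:2, n * k, replace = TRUE), ncol = k,
                  dimnames = list(NULL, sprintf("metric_%d", 1:k)))
      theta <- sample(c(0.05, 0.1, 0.25, 0.5), 1)
    })
    got <- mine_frequent_patterns(m, theta = theta)
    want <- brute_force_frequent(m, theta)
    expect_setequal(got$pattern_id, as.character(names(want)))
    if (nrow(got) > 0)
      expect_equal(got$count, unname(unlist(want[got$pattern_id])))
  }
})

test_that("every subset of a frequent pattern is frequent (anti-monotone)", {
  withr::with_seed(77, {
    m <- matrix(sample(0:2, 150 * 4, replace = TRUE), ncol = 4,
                dimnames = list(NULL, sprintf("metric_%d", 1:4)))
  })
  out <- mine_frequent_patterns(m, theta = 0.05)
  ids <- out$pattern_id
  for (r in which(out$length > 1)) {
    mets <- out$metrics[[r]]; bins <- out$bins[[r]]
    for (drop in seq_along(mets)) {
      sub_id <- paste(sprintf("m%d=%d", mets[-drop], bins[-drop]),
                      collapse = "|")
      expect_true(sub_id %in% ids)
      expect_gte(out$support[match(sub_id, ids)], out$support[r])
    }
  }
})

test_that("pattern_support counts matching rows", {
  m <- matrix(c(0L, 1L,
                0L, 1L,
                0L, 0L,
                1L, 1L), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("metric_1", "metric_2")))
  p <- list(metrics = c(1L, 2L), bins = c(0L, 1L))
  expect_equal(pattern_support(m, p), 0.5)
  expect_error(pattern_support(m[0, , drop = FALSE], p), "empty")
})

test_that("discriminative selection keeps signal and applies the direction rule", {
  n <- 20
  withr::with_seed(5, {
    signal <- c(rnorm(n, 0.30, 0.02), rnorm(n, 0.05, 0.02))
    flat <- rep(0.1, 2 * n)
    wrong_dir <- c(rnorm(n, 0.05, 0.02), rnorm(n, 0.30, 0.02))
  })
  freqs <- tibble::tibble(group = sprintf("P%02d", 1:(2 * n)),
                          n_pixels = 500L,
                          sig = signal, flat = flat, wrong = wrong_dir)
  labels <- setNames(rep(c(TRUE, FALSE), each = n), freqs$group)
  pat <- tibble::tibble(pattern_id = c("sig", "flat", "wrong"),
                        metrics = list(1L, 2L, 3L), bins = list(0L, 1L, 2L),
                        length = 1L, count = 1L, support = 0.1,
                        class = c("case", "case", "case"))
  out <- select_discriminative_patterns(freqs, labels, pat, m = 10)
  expect_equal(out$pattern_id, "sig")   # flat fails stage 1, wrong fails stage 2
  expect_equal(out$rank, 1L)
  # all-constant frequencies leave nothing
  expect_warning(
    empty <- select_discriminative_patterns(
      freqs, labels, pat[pat$pattern_id == "flat", ], m = 10),
    "no discriminative")
  expect_equal(nrow(empty), 0)
})

test_that("pattern features are per-sample match fractions", {
  m <- matrix(c(rep(c(1L, 1L), 3), rep(c(0L, 1L), 7)), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("metric_1", "metric_2")))
  d <- dplyr::bind_cols(tibble::tibble(core_id = rep("c1", 10)),
                        tibble::as_tibble(m))
  pat <- tibble::tibble(pattern_id = c("both", "none", "m2"),
                        metrics = list(c(1L, 2L), 1L, 2L),
                        bins = list(c(1L, 1L), 2L, 1L),
                        length = c(2L, 1L, 1L), count = 1L, support = 0.1)
  f <- compute_pattern_features(d, pat)
  expect_equal(f$both, 0.3)
  expect_equal(f$none, 0.0)
  expect_equal(f$m2, 1.0)
})

test_that("feature values are invariant to pixel order", {
  coh <- tiny_cohort(n_pairs = 3, seed = 8)
  sch <- fit_discretizer(coh$pixels, n_bins = 5)
  disc <- discretize(coh$pixels, sch)
  pats <- mine_frequent_patterns(disc, theta = 0.1, max_len = 2)
  f1 <- compute_pattern_features(disc, pats)
  shuffled <- withr::with_seed(1, disc[sample(nrow(disc)), ])
  f2 <- compute_pattern_features(shuffled, pats)
  f2 <- f2[match(f1$core_id, f2$core_id), ]
  expect_equal(as.data.frame(f2), as.data.frame(f1), ignore_attr = TRUE)
})

test_that("stage-1 retention rate matches alpha on null frequencies", {
  # per-subject frequencies drawn iid in both classes: the two-sided
  # rank-sum should reject at ~alpha1
  n_pat <- 400; n_sub <- 60
  withr::with_seed(31, {
    fm <- matrix(rbeta(n_sub * n_pat, 2, 20), nrow = n_sub)
  })
  freqs <- dplyr::bind_cols(
    tibble::tibble(group = sprintf("P%02d", 1:n_sub), n_pixels = 300L),
    tibble::as_tibble(matrix(fm, n_sub, n_pat,
                             dimnames = list(NULL, sprintf("p%03d", 1:n_pat)))))
  labels <- setNames(rep(c(TRUE, FALSE), each = n_sub / 2), freqs$group)
  pat <- tibble::tibble(pattern_id = sprintf("p%03d", 1:n_pat),
                        metrics = replicate(n_pat, 1L, simplify = FALSE),
                        bins = replicate(n_pat, 0L, simplify = FALSE),
                        length = 1L, count = 1L, support = 0.1,
                        class = "case")
  out <- suppressWarnings(
    select_discriminative_patterns(freqs, labels, pat, m = n_pat,
                                   alpha1 = 0.05))
  # survivors of stage 1 (before direction filtering) ~ alpha1 * n_pat;
  # direction filter then halves them, so test the stage-1 rate directly
  fmx <- as.matrix(freqs[, pat$pattern_id])
  p1 <- irscore:::rank_sum_p(fmx, labels[freqs$group], "two.sided")
  rate <- mean(p1 < 0.05)
  se <- sqrt(0.05 * 0.95 / n_pat)
  expect_lt(abs(rate - 0.05), 3 * se)
  expect_lte(nrow(out), sum(p1 < 0.05))
})

test_that("patterns serialize to JSON", {
  m <- matrix(c(0L, 0L, 1L, 1L), ncol = 2,
              dimnames = list(NULL, c("metric_1", "metric_2")))
  pats <- mine_frequent_patterns(m, theta = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_patterns(pats, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  expect_equal(length(back), nrow(pats))
  expect_equal(back[[1]]$pattern_id, pats$pattern_id[1])
})
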