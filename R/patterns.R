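#' Mine frequent patterns with FP-growth
#'
#' A pattern is a set of (metric, bin) items; a pixel matches when every
#' listed metric has exactly the listed bin value. A pattern is frequent
#' when its match count is at least `ceiling(theta * n)` over the `n`
#' pixels. Mining returns exactly the frequent set (verified against
#' exhaustive enumeration in the test suite), canonically ordered by
#' pattern length then lexicographically by items.
#'
#' @param data Discretized pixel tibble (integer bins, see [discretize()])
#'   or integer matrix.
#' @param theta Minimum support fraction in (0, 1].
#' @param max_len Maximum pattern length (number of items); `Inf` for
#'   unbounded.
#' @param cols Metric columns, as in [fit_discretizer()].
#' @return Tibble of class `ir_patterns` with columns `pattern_id`,
#'   `metrics` (list of integer vectors, 1-based metric index), `bins`
#'   (list, 0-based bin values), `length`, `count`, `support`.
#' @export
mine_frequent_patterns <- function(data, theta = 0.02, max_len = Inf,
                                   cols = NULL) {
  if (!is.numeric(theta) || theta <= 0 || theta > 1)
    stop("`theta` must be in (0, 1]")
  m <- metric_matrix(data, cols)
  storage.mode(m) <- "integer"
  if (nrow(m) < 1) stop("empty matrix")
  n_levels <- max(m) + 1L
  ml <- if (is.finite(max_len)) as.integer(max_len) else ncol(m)
  res <- fpgrowth_mine_cpp(m, n_levels, theta, ml)
  if (length(res$lengths) == 0) {
    return(empty_patterns())
  }
  ends <- cumsum(res$lengths)
  starts <- ends - res$lengths + 1L
  items <- purrr::map2(starts, ends, ~res$items[.x:.y])
  metrics <- purrr::map(items, ~as.integer(.x %/% n_levels) + 1L)
  bins <- purrr::map(items, ~as.integer(.x %% n_levels))
  out <- tibble::tibble(
    pattern_id = purrr::map2_chr(metrics, bins,
                                 ~paste(sprintf("m%d=%d", .x, .y), collapse = "|")),
    metrics = metrics, bins = bins,
    length = as.integer(res$lengths),
    count = as.integer(res$counts),
    support = res$counts / res$n)
  key <- vapply(items, function(x) paste(sprintf("%06d", x), collapse = ","),
                character(1))
  out <- out[order(out$length, key), , drop = FALSE]
  class(out) <- c("ir_patterns", class(out))
  out
}

empty_patterns <- function() {
  out <- tibble::tibble(pattern_id = character(), metrics = list(),
                        bins = list(), length = integer(),
                        count = integer(), support = double())
  class(out) <- c("ir_patterns", class(out))
  out
}

#' Support of one pattern in a discretized dataset
#'
#' @param data Discretized pixel tibble or integer matrix.
#' @param pattern One row of an `ir_patterns` tibble, or a list with
#'   `metrics` (1-based) and `bins` (0-based) integer vectors.
#' @param cols Metric columns, as in [fit_discretizer()].
#' @return Fraction of rows matching all items, in `[0, 1]`.
#' @export
pattern_support <- function(data, pattern, cols = NULL) {
  m <- metric_matrix(data, cols)
  if (nrow(m) < 1) stop("empty matrix")
  it <- pattern_items(pattern)
  match <- rep(TRUE, nrow(m))
  for (l in seq_along(it$metrics))
    match <- match & (m[, it$metrics[l]] == it$bins[l])
  mean(match)
}

pattern_items <- function(pattern) {
  if (is.data.frame(pattern)) {
    stopifnot(nrow(pattern) == 1)
    list(metrics = pattern$metrics[[1]], bins = pattern$bins[[1]])
  } else {
    list(metrics = pattern$metrics, bins = pattern$bins)
  }
}

#' Per-group pattern match frequencies
#'
#' Counts, for every pattern, the matching pixels within each group (core
#' or patient) and divides by the group's pixel count.
#'
#' @param data Discretized pixel tibble (or integer matrix via `cols`).
#' @param patterns An `ir_patterns` tibble.
#' @param group Grouping vector (e.g. core or patient ids), one per row; or
#'   the name of a column of `data`.
#' @param cols Metric columns, as in [fit_discretizer()].
#' @return Tibble with column `group`, `n_pixels`, and one frequency column
#'   per `pattern_id`.
#' @export
pattern_frequencies <- function(data, patterns, group, cols = NULL) {
  m <- metric_matrix(data, cols)
  storage.mode(m) <- "integer"
  if (is.character(group) && length(group) == 1 &&
      !is.matrix(data) && group %in% names(data))
    group <- data[[group]]
  stopifnot(length(group) == nrow(m))
  lev <- unique(group)                 # first-occurrence order
  gi <- match(group, lev)
  counts <- pattern_match_counts_cpp(
    m, gi - 1L, length(lev),
    lapply(patterns$metrics, function(x) as.integer(x - 1L)),
    lapply(patterns$bins, as.integer))
  sizes <- tabulate(gi, nbins = length(lev))
  freq <- counts / sizes
  colnames(freq) <- patterns$pattern_id
  dplyr::bind_cols(tibble::tibble(group = lev, n_pixels = sizes),
                   tibble::as_tibble(freq))
}

# Vectorized two-sample Wilcoxon rank-sum p-values over the columns of a
# matrix (normal approximation with continuity correction). `positive`
# flags the rows of the first sample. With `correct_ties` the variance is
# tie-corrected (the proper test, used at stage 1); without it the p-value
# is a strictly monotone function of the U statistic for fixed group
# sizes, which is what the stage-2 ordering needs (tie-corrected p-values
# would rank zero-inflated patterns incomparably).
rank_sum_p <- function(mat, positive,
                       alternative = c("two.sided", "greater"),
                       correct_ties = TRUE) {
  alternative <- match.arg(alternative)
  n1 <- sum(positive); n2 <- sum(!positive); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  apply(mat, 2, function(x) {
    r <- rank(x)
    w <- sum(r[positive]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of group 1
    mu <- n1 * n2 / 2
    sigma2 <- if (correct_ties) {
      ties <- tabulate(match(x, x))
      ties <- ties[ties > 0]
      (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    } else {
      n1 * n2 * (n + 1) / 12
    }
    if (sigma2 <= 0) return(1)
    z_num <- w - mu
    cc <- sign(z_num) * 0.5
    z <- (z_num - cc) / sqrt(sigma2)
    switch(alternative,
           two.sided = 2 * pnorm(-abs(z)),
           greater = pnorm(z, lower.tail = FALSE))
  })
}

#' Two-stage selection of discriminative patterns
#'
#' Stage 1 keeps patterns whose per-subject match frequency distribution
#' differs between recurrence classes (two-sided Wilcoxon rank-sum,
#' `p < alpha1`). Stage 2 keeps those whose frequencies shift toward the
#' pattern's source class (one-sided rank-sum in the source-class
#' direction). Survivors are ranked by the stage-2 p-value (ascending),
#' ties broken by absolute mean-frequency difference then canonical pattern
#' order, and the top `m` are returned.
#'
#' @param freqs Per-subject frequency tibble from [pattern_frequencies()]
#'   (grouped by patient), with `group` holding patient ids.
#' @param labels Named logical vector (`TRUE` = recurrence) or tibble with
#'   `patient_id` and `recurrence` columns.
#' @param patterns The `ir_patterns` tibble the frequencies were computed
#'   for, carrying a `class` column (`"case"` or `"control"`, the class the
#'   pattern was mined in).
#' @param m Number of patterns to retain.
#' @param alpha1 Stage-1 significance level.
#' @return The retained subset of `patterns` with columns `p_stage1`,
#'   `p_stage2`, `effect` (mean case minus control frequency) and `rank`;
#'   empty (with a warning) when nothing survives.
#' @export
select_discriminative_patterns <- function(freqs, labels, patterns,
                                           m = 100, alpha1 = 0.05) {
  stopifnot(m >= 1, alpha1 > 0, alpha1 < 1)
  if (is.data.frame(labels))
    labels <- setNames(labels$recurrence, labels$patient_id)
  lab <- labels[freqs$group]
  if (any(is.na(lab))) stop("labels missing for some subjects")
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("need at least two subjects per class")
  fm <- as.matrix(freqs[, patterns$pattern_id, drop = FALSE])
  p1 <- rank_sum_p(fm, lab, "two.sided")
  effect <- colMeans(fm[lab, , drop = FALSE]) - colMeans(fm[!lab, , drop = FALSE])
  # stage 2: one-sided, direction of the source class
  p2 <- numeric(ncol(fm))
  case_dir <- patterns$class == "case"
  if (any(case_dir))
    p2[case_dir] <- rank_sum_p(fm[, case_dir, drop = FALSE], lab, "greater",
                               correct_ties = FALSE)
  if (any(!case_dir))
    p2[!case_dir] <- rank_sum_p(fm[, !case_dir, drop = FALSE], !lab, "greater",
                                correct_ties = FALSE)
  keep <- p1 < alpha1 & p2 < 0.5
  out <- patterns[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no discriminative patterns survive the two-stage test")
    out$p_stage1 <- double(); out$p_stage2 <- double()
    out$effect <- double(); out$rank <- integer()
    return(out)
  }
  out$p_stage1 <- p1[keep]
  out$p_stage2 <- p2[keep]
  out$effect <- effect[keep]
  ord <- order(out$p_stage2, -abs(out$effect), seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out <- head(out, m)
  out$rank <- seq_len(nrow(out))
  out
}

#' Pattern-frequency feature vectors per tissue sample
#'
#' The feature value of pattern j for a sample (core) is the fraction of
#' the sample's pixels matching pattern j.
#'
#' @param data Discretized pixel tibble.
#' @param patterns Retained `ir_patterns`.
#' @param sample_col Column of `data` identifying the sample (default
#'   `"core_id"`).
#' @param cols Metric columns, as in [fit_discretizer()].
#' @return Tibble with the sample id column, `n_pixels`, and one feature
#'   column per pattern (values in `[0, 1]`).
#' @export
compute_pattern_features <- function(data, patterns, sample_col = "core_id",
                                     cols = NULL) {
  if (nrow(patterns) == 0) stop("`patterns` is empty")
  if (nrow(data) == 0) stop("sample has no pixels")
  out <- pattern_frequencies(data, patterns, data[[sample_col]], cols)
  names(out)[1] <- sample_col
  out
}

#' Serialize patterns to JSON
#' @param patterns An `ir_patterns` tibble (optionally with selection
#'   statistics).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  x <- purrr::pmap(patterns, function(...) {
    row <- list(...)
    row$metrics <- as.integer(row$metrics)
    row$bins <- as.integer(row$bins)
    row
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
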