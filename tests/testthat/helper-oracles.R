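# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive frequent-itemset enumeration: all (metric, bin) itemsets with
# support >= theta, by brute force over every combination of metrics and
# bin values present in the data.
brute_force_frequent <- function(disc, theta, max_len = Inf) {
  n <- nrow(disc); k <- ncol(disc)
  min_count <- ceiling(theta * n - 1e-9)
  out <- list()
  for (len in seq_len(min(k, max_len))) {
    for (ms in utils::combn(k, len, simplify = FALSE)) {
      vals <- lapply(ms, function(j) sort(unique(disc[, j])))
      grids <- expand.grid(vals)
      for (r in seq_len(nrow(grids))) {
        bins <- as.integer(grids[r, ])
        match <- rep(TRUE, n)
        for (l in seq_len(len)) match <- match & (disc[, ms[l]] == bins[l])
        cnt <- sum(match)
        if (cnt >= min_count) {
          id <- paste(sprintf("m%d=%d", ms, bins), collapse = "|")
          out[[id]] <- cnt
        }
      }
    }
  }
  out
}

# Pairwise-counting Mann-Whitney U of x over y (0.5 credit for ties).
u_statistic <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Trapezoid integral by explicit summation.
trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

# Maximum ECDF gap between two samples.
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Small synthetic cohort for unit tests (kept tiny for speed).
tiny_cohort <- function(n_pairs = 8, seed = 1, planted = list(),
                        n_metrics = 6, pixels = c(60, 90)) {
  generate_cohort(cohort_config(
    n_pairs = n_pairs, cores_per_patient = c(2, 3),
    pixels_per_core = pixels, n_metrics = n_metrics,
    planted_patterns = planted, seed = seed))
}

# Pipeline settings sized for tiny cohorts.
tiny_pipeline <- function(...) {
  pipeline_config(max_len = 3, k0 = 10, ...)
}

# A clinical table hitting CAPRA-S extremes and categories.
capra_fixture <- function() {
  tibble::tibble(
    patient_id = c("A", "B", "C"),
    psa = c(25, 4, 15),
    gleason_primary = c(4, 3, 3),
    gleason_secondary = c(5, 3, 4),
    margin = c(TRUE, FALSE, FALSE),
    svi = c(TRUE, FALSE, FALSE),
    ece = c(TRUE, FALSE, FALSE),
    lni = c(TRUE, FALSE, FALSE))
}
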