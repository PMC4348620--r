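# Mutual information helpers: features (frequencies in [0,1]) are quantized
# to quantile bins before plug-in MI estimation.

quantile_bin <- function(x, n_bins = 10) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

# xb, yb: positive integer bin codes
mutual_info <- function(xb, yb) {
  nx <- max(xb); ny <- max(yb); n <- length(xb)
  joint <- tabulate((xb - 1L) * ny + yb, nbins = nx * ny) / n
  px <- tabulate(xb, nx) / n
  py <- tabulate(yb, ny) / n
  pxy_ind <- as.vector(outer(py, px))   # column-major: y fast index
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / pxy_ind[pos]))
}

#' Stage-1 feature ranking: maximal relevance, minimal redundancy
#'
#' Greedy mRMR ordering of pattern-frequency features: the first feature
#' maximizes mutual information with the class label; each subsequent
#' feature maximizes relevance minus its mean mutual information with the
#' already-selected features. Features are quantized to 10 quantile bins
#' for MI estimation. Deterministic given the input (ties broken by column
#' order).
#'
#' @param data Tibble containing a logical `recurrence` column and the
#'   feature columns (id columns `core_id`, `patient_id`, `pair_id`,
#'   `n_pixels` are ignored).
#' @param k0 Target subset size; when larger than the number of features,
#'   all are returned with a warning.
#' @param n_bins Quantile bins for MI estimation.
#' @return Tibble (ordered, one row per selected feature) with columns
#'   `feature`, `relevance`, `redundancy`, `score`, `step`.
#' @export
rank_relevance_redundancy <- function(data, k0 = 30, n_bins = 10) {
  feats <- feature_cols(data)
  if (length(unique(data$recurrence)) < 2)
    stop("both classes must be present")
  if (k0 > length(feats)) {
    warning("k0 exceeds the number of features; returning all")
    k0 <- length(feats)
  }
  yb <- as.integer(data$recurrence) + 1L
  xb <- lapply(feats, function(f) quantile_bin(data[[f]], n_bins))
  names(xb) <- feats
  relevance <- vapply(xb, mutual_info, numeric(1), yb = yb)
  selected <- character(0)
  red_sum <- setNames(numeric(length(feats)), feats)
  out <- vector("list", k0)
  remaining <- feats
  for (step in seq_len(k0)) {
    red <- if (length(selected) == 0) red_sum[remaining] * 0
           else red_sum[remaining] / length(selected)
    score <- relevance[remaining] - red
    best <- remaining[which.max(score)]
    out[[step]] <- tibble::tibble(feature = best,
                                  relevance = unname(relevance[best]),
                                  redundancy = unname(red[best]),
                                  score = unname(score[best]),
                                  step = step)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    for (f in remaining)
      red_sum[f] <- red_sum[f] + mutual_info(xb[[f]], xb[[best]])
  }
  dplyr::bind_rows(out)
}

feature_cols <- function(data) {
  meta <- c("core_id", "patient_id", "pair_id", "recurrence", "n_pixels",
            "group", "fold")
  nms <- setdiff(names(data), meta)
  nms[vapply(data[nms], is.numeric, logical(1))]
}

# Inner-CV pairwise ranking accuracy of a feature subset: folds over matched
# pairs; within each held-out pair every (case core, control core)
# comparison scores a success when the case core ranks higher.
cv_pair_rank_accuracy <- function(data, feats, folds = 3, seed = 1, cost = 1) {
  pairs <- unique(data$pair_id)
  if (length(pairs) < folds) folds <- max(2, length(pairs))
  fold_of <- withr::with_seed(seed,
    sample(rep_len(seq_len(folds), length(pairs))))
  names(fold_of) <- pairs
  correct <- 0; total <- 0
  for (k in seq_len(folds)) {
    test_pairs <- pairs[fold_of == k]
    train <- data[!data$pair_id %in% test_pairs, , drop = FALSE]
    test <- data[data$pair_id %in% test_pairs, , drop = FALSE]
    if (length(unique(train$recurrence)) < 2) stop("degenerate inner fold")
    model <- try(train_ranking_svm(train, features = feats, cost = cost),
                 silent = TRUE)
    if (inherits(model, "try-error")) next
    sc <- predict(model, test)
    for (pr in test_pairs) {
      sel <- test$pair_id == pr
      s_case <- sc[sel & test$recurrence]
      s_ctrl <- sc[sel & !test$recurrence]
      if (length(s_case) == 0 || length(s_ctrl) == 0) next
      cmp <- outer(s_case, s_ctrl, ">")
      correct <- correct + sum(cmp)
      total <- total + length(cmp)
    }
  }
  if (total == 0) return(0)
  correct / total
}

#' Stage-2 refinement: sequential floating add/remove search
#'
#' Starting from an initial feature subset, alternately tries adding each
#' unselected feature and removing each selected feature; a step is
#' accepted only when the inner-cross-validated pairwise ranking accuracy
#' improves by more than `tol`. The objective trace is therefore
#' non-decreasing and the search terminates (monotone objective plus
#' iteration cap).
#'
#' @param data Per-core feature tibble with `pair_id`, `patient_id`,
#'   `recurrence` and feature columns.
#' @param initial Character vector of starting features (non-empty).
#' @param folds Inner-CV folds over matched pairs.
#' @param max_iter Maximum add/remove sweeps.
#' @param tol Minimum accepted improvement.
#' @param seed Seed for inner fold assignment.
#' @param cost Ranking-SVM margin parameter.
#' @return List of class `ir_refine`: `selected` (character), `trace`
#'   (numeric objective after each accepted step), `objective`.
#' @export
refine_subset <- function(data, initial, folds = 3, max_iter = 5,
                          tol = 1e-6, seed = 1, cost = 1) {
  stopifnot(length(initial) >= 1)
  feats_all <- feature_cols(data)
  selected <- intersect(initial, feats_all)
  if (length(selected) == 0) stop("no valid initial features")
  obj <- cv_pair_rank_accuracy(data, selected, folds, seed, cost)
  trace <- obj
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (f in setdiff(feats_all, selected)) {
      cand <- cv_pair_rank_accuracy(data, c(selected, f), folds, seed, cost)
      if (cand > obj + tol) {
        selected <- c(selected, f); obj <- cand; trace <- c(trace, obj)
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      for (f in selected) {
        cand <- cv_pair_rank_accuracy(data, setdiff(selected, f),
                                      folds, seed, cost)
        if (cand > obj + tol) {
          selected <- setdiff(selected, f); obj <- cand; trace <- c(trace, obj)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  structure(list(selected = selected, trace = trace, objective = obj),
            class = "ir_refine")
}

#' @exportS3Method base::print
print.ir_refine <- function(x, ...) {
  cat(sprintf("<ir_refine> %d features, objective %.4f (%d accepted steps)\n",
              length(x$selected), x$objective, length(x$trace) - 1))
  invisible(x)
}

#' Write a feature-selection report to JSON
#' @param ranking Output of [rank_relevance_redundancy()].
#' @param refine Optional [refine_subset()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(ranking, path, refine = NULL) {
  x <- list(ranking = ranking,
            refined = if (!is.null(refine))
              list(selected = refine$selected, trace = refine$trace))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
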