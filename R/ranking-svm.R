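#' Train a linear Ranking-SVM on case/control core samples
#'
#' Reduces the learning-to-rank problem to a linear SVM on difference
#' vectors: for every (case core s, control core t) ordering constraint,
#' the examples (s - t, +1) and (t - s, -1) are added, so the fitted
#' hyperplane through the origin encodes the scoring function f with
#' f(case) > f(control) by a margin. When `pair_id` is present the
#' constraints are restricted to within matched pairs; otherwise all
#' case-control core combinations are used, subsampled (seeded) to
#' `max_constraints`. Features are z-scored on the training data, so the
#' induced sample ordering is invariant to affine feature rescaling when
#' the model is refit.
#'
#' @param data Per-core tibble with a logical `recurrence` column, optional
#'   `pair_id`, and numeric feature columns.
#' @param features Character vector of feature column names; default all
#'   non-metadata numeric columns.
#' @param cost SVM margin parameter C.
#' @param max_constraints Cap on ordering constraints for unpaired
#'   training.
#' @param seed Seed for constraint subsampling.
#' @return Object of class `ranking_model`: feature weights, scaler,
#'   training pairwise accuracy.
#' @export
train_ranking_svm <- function(data, features = NULL, cost = 1,
                              max_constraints = 1e5, seed = 1) {
  features <- features %||% feature_cols(data)
  if (length(features) == 0) stop("no feature columns")
  x <- as.matrix(data[, features, drop = FALSE])
  y <- data$recurrence
  if (sum(y) < 1 || sum(!y) < 1) stop("need cores from both classes")
  centre <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")

  if (!is.null(data$pair_id)) {
    idx <- do.call(rbind, lapply(split(seq_len(nrow(data)), data$pair_id),
      function(ii) {
        ca <- ii[y[ii]]; co <- ii[!y[ii]]
        if (length(ca) == 0 || length(co) == 0) return(NULL)
        as.matrix(expand.grid(case = ca, control = co))
      }))
  } else {
    idx <- as.matrix(expand.grid(case = which(y), control = which(!y)))
  }
  if (is.null(idx) || nrow(idx) == 0) stop("no ordering constraints available")
  if (nrow(idx) > max_constraints) {
    keep <- withr::with_seed(seed, sample(nrow(idx), max_constraints))
    idx <- idx[keep, , drop = FALSE]
  }
  diffs <- xs[idx[, 1], , drop = FALSE] - xs[idx[, 2], , drop = FALSE]
  if (all(abs(diffs) < 1e-12))
    stop("degenerate model: all case/control samples have identical features")
  xx <- rbind(diffs, -diffs)
  yy <- factor(rep(c(1, -1), each = nrow(diffs)))
  fit <- e1071::svm(xx, yy, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  # svm() labels the first factor level +1 internally; align sign so that
  # case-minus-control differences score positive
  if (mean(diffs %*% w > 0) < 0.5) w <- -w
  scores <- as.numeric(xs %*% w)
  train_acc <- mean(scores[idx[, 1]] > scores[idx[, 2]])
  structure(list(weights = setNames(w, features), centre = centre,
                 scale = scale_, features = features, cost = cost,
                 n_constraints = nrow(idx),
                 training_accuracy = train_acc),
            class = "ranking_model")
}

#' @exportS3Method base::print
print.ranking_model <- function(x, ...) {
  cat(sprintf("<ranking_model> linear, %d features, C = %g, training pairwise accuracy %.3f\n",
              length(x$weights), x$cost, x$training_accuracy))
  invisible(x)
}

#' Score samples with a fitted ranking model
#' @param object A `ranking_model`.
#' @param newdata Tibble with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of scores (higher = more recurrence-like).
#' @export
predict.ranking_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("newdata is missing features: ", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$centre), 2, object$scale, "/")
  as.numeric(xs %*% object$weights)
}

#' @export
tidy.ranking_model <- function(x, ...) {
  tibble::tibble(term = names(x$weights), estimate = unname(x$weights))
}

#' @export
glance.ranking_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights), cost = x$cost,
                 n_constraints = x$n_constraints,
                 training_accuracy = x$training_accuracy)
}

#' Assign ranks 1..N to samples
#'
#' Rank N is the highest-scoring (most recurrence-like) sample and rank 1
#' the lowest. Tied scores keep their stable input order, with a warning.
#'
#' @param model A `ranking_model`.
#' @param data Tibble of samples with the model's features.
#' @return `data` with appended `score` and `rank` columns.
#' @export
rank_samples <- function(model, data) {
  if (nrow(data) < 1) stop("no samples")
  s <- predict(model, data)
  if (anyDuplicated(s)) warning("tied scores; ties broken by input order")
  data$score <- s
  data$rank <- rank(s, ties.method = "first")
  data
}

#' Preference score between two patients' core sets
#'
#' The pooled core scores of the two patients are ranked together (average
#' ranks on ties); the preference of patient 1 against patient 2 is the sum
#' of the d-th powers of the ranks held by patient 1's cores. The minimum
#' (all of S1 at the bottom) and maximum (all of S1 at the top) attainable
#' sums normalize it to nPreference in `[0, 1]`. With d = 1 and no ties,
#' nPreference equals the normalized Mann-Whitney U statistic of S1 over
#' S2, and nPref(p1;p2) + nPref(p2;p1) = 1.
#'
#' @param scores1,scores2 Numeric score vectors for the cores of patients 1
#'   and 2 (both non-empty), on a common model scale.
#' @param d Rank exponent, >= 1.
#' @return List of class `ir_preference`: `preference`, `pref_min`,
#'   `pref_max`, `npreference`, `d`, `n1`, `n2`.
#' @export
preference_score <- function(scores1, scores2, d = 1) {
  if (length(scores1) < 1 || length(scores2) < 1)
    stop("both core sets must be non-empty")
  if (!is.numeric(d) || d < 1) stop("`d` must be >= 1")
  n1 <- length(scores1); n2 <- length(scores2)
  r <- rank(c(scores1, scores2), ties.method = "average")
  pref <- sum(r[seq_len(n1)]^d)
  pref_min <- sum(seq_len(n1)^d)
  pref_max <- sum(seq(n2 + 1, n2 + n1)^d)
  npref <- if (pref_max > pref_min)
    (pref - pref_min) / (pref_max - pref_min) else 0.5
  npref <- min(max(npref, 0), 1)
  structure(list(preference = pref, pref_min = pref_min, pref_max = pref_max,
                 npreference = npref, d = d, n1 = n1, n2 = n2),
            class = "ir_preference")
}

#' @exportS3Method base::print
print.ir_preference <- function(x, ...) {
  cat(sprintf("<ir_preference> Preference %.3f in [%.3f, %.3f], nPreference %.3f (d = %g)\n",
              x$preference, x$pref_min, x$pref_max, x$npreference, x$d))
  invisible(x)
}

#' Normalized preference of one score set over another
#' @inheritParams preference_score
#' @return `npreference` as a single number in `[0, 1]`.
#' @export
npreference <- function(scores1, scores2, d = 1) {
  preference_score(scores1, scores2, d)$npreference
}
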