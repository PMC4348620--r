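#' Cross-validation configuration
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(k = 10, seed = 1) {
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_config")
}

#' Nested case-control pair cross-validation
#'
#' Folds are formed over matched pairs (a pair is never split). For each
#' held-out pair the pipeline trained on the remaining pairs computes the
#' normalized preference of patient A against patient B; the patient with
#' nPreference > 0.5 is predicted to be the case. An exact tie at 0.5 is
#' counted as a failure (conservative) and reported. Significance of the
#' accuracy is the one-sided exact binomial tail
#' `P(X >= correct | n, 0.5)`.
#'
#' @param cohort An `ir_cohort` (or list with `clinical` and `pixels`).
#' @param pipeline A [pipeline_config()].
#' @param cv A [cv_config()].
#' @return Object of class `ir_nested_cv` with per-pair results, overall
#'   `accuracy`, `n`, and binomial `p_value`.
#' @export
nested_cv_pair_accuracy <- function(cohort, pipeline = pipeline_config(),
                                    cv = cv_config()) {
  clinical <- cohort$clinical; pixels <- cohort$pixels
  pairs <- unique(clinical$pair_id)
  k <- min(cv$k, length(pairs))
  if (k < 2) stop("need at least 2 folds")
  fold_of <- withr::with_seed(cv$seed,
                              sample(rep_len(seq_len(k), length(pairs))))
  names(fold_of) <- pairs
  res <- vector("list", k)
  for (f in seq_len(k)) {
    test_pairs <- pairs[fold_of == f]
    tr_cl <- clinical[!clinical$pair_id %in% test_pairs, , drop = FALSE]
    tr_px <- pixels[pixels$patient_id %in% tr_cl$patient_id, , drop = FALSE]
    fit <- fit_ir_pipeline(tr_px, tr_cl, pipeline)
    res[[f]] <- purrr::map_dfr(test_pairs, function(pr) {
      pcl <- clinical[clinical$pair_id == pr, , drop = FALSE]
      case_id <- pcl$patient_id[pcl$recurrence]
      ctrl_id <- pcl$patient_id[!pcl$recurrence]
      np <- npreference_patients(fit, pixels, case_id, ctrl_id)$npreference
      tibble::tibble(pair_id = pr, fold = f, case_id = case_id,
                     control_id = ctrl_id, npref_case = np,
                     tie = np == 0.5, correct = np > 0.5)
    })
  }
  res <- dplyr::bind_rows(res)
  n <- nrow(res); correct <- sum(res$correct)
  n_ties <- sum(res$tie)
  if (n_ties > 0)
    message(sprintf("%d exact nPreference ties counted as failures", n_ties))
  p <- binom.test(correct, n, p = 0.5, alternative = "greater")$p.value
  # accuracy over decided (non-tied) pairs: with small per-patient core
  # sets the pooled rank sum can hit its midpoint exactly, so the decided
  # accuracy is the quantity a Binomial(n_decided, 0.5) null describes
  n_dec <- n - n_ties
  structure(list(results = res, accuracy = correct / n, n = n,
                 n_ties = n_ties,
                 accuracy_decided = if (n_dec > 0) correct / n_dec else NA_real_,
                 n_decided = n_dec,
                 p_value = p),
            class = "ir_nested_cv")
}

#' @exportS3Method base::print
print.ir_nested_cv <- function(x, ...) {
  cat(sprintf("<ir_nested_cv> %d/%d pairs correct (accuracy %.3f), binomial p = %.3g\n",
              round(x$accuracy * x$n), x$n, x$accuracy, x$p_value))
  invisible(x)
}

#' @export
tidy.ir_nested_cv <- function(x, ...) x$results

#' @export
glance.ir_nested_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n, n_ties = x$n_ties,
                 accuracy_decided = x$accuracy_decided,
                 n_decided = x$n_decided, p_value = x$p_value)
}

#' K-fold query cross-validation producing per-patient IR Scores
#'
#' Folds are stratified by recurrence; in each fold the pipeline and the
#' logistic IR Score model are fitted on the other K-1 partitions and the
#' held-out patients are scored as individual queries. Every patient is
#' scored exactly once by a model never trained on them. `k` equal to the
#' number of patients gives leave-one-out.
#'
#' @inheritParams nested_cv_pair_accuracy
#' @return Tibble of class `ir_query_cv`: `patient_id`, `recurrence`,
#'   `fold`, `npref_recurrent`, `npref_nonrecurrent`, `ir_score`.
#' @export
kfold_query_cv <- function(cohort, pipeline = pipeline_config(),
                           cv = cv_config()) {
  clinical <- cohort$clinical; pixels <- cohort$pixels
  n <- nrow(clinical)
  k <- min(cv$k, n)
  # stratified assignment: spread each class over the folds
  fold_of <- withr::with_seed(cv$seed, {
    f <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(clinical$recurrence == cls))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr_cl <- clinical[fold_of != f, , drop = FALSE]
    te_cl <- clinical[fold_of == f, , drop = FALSE]
    if (nrow(te_cl) == 0) next
    if (sum(tr_cl$recurrence) < 2 || sum(!tr_cl$recurrence) < 2)
      stop("a training split lost a class; use fewer folds")
    tr_px <- pixels[pixels$patient_id %in% tr_cl$patient_id, , drop = FALSE]
    te_px <- pixels[pixels$patient_id %in% te_cl$patient_id, , drop = FALSE]
    fit <- fit_ir_pipeline(tr_px, tr_cl, pipeline)
    ir <- fit_ir_score_model(tr_cl, pipeline_scores(fit), d = pipeline$d)
    pred <- predict(ir, te_cl, pipeline_scores(fit, te_px))
    pred$recurrence <- te_cl$recurrence[match(pred$patient_id, te_cl$patient_id)]
    pred$fold <- f
    out[[f]] <- pred
  }
  out <- dplyr::bind_rows(out)
  out <- dplyr::relocate(out, "patient_id", "recurrence", "fold")
  class(out) <- c("ir_query_cv", class(out))
  out
}

# Empirical AUC by the tie-corrected rank statistic (equals the normalized
# Mann-Whitney U with 0.5 credit for ties).
auc_empirical <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 >= 1, n0 >= 1)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with empirical and binormal-smoothed AUC
#'
#' The empirical AUC is the tie-corrected rank (Mann-Whitney) estimate.
#' The smoothed AUC fits a normal distribution to the scores of each class
#' (binormal model) and evaluates
#' `pnorm((mu1 - mu0) / sqrt(s0^2 + s1^2))`, compensating for the
#' granularity-driven underestimation of empirical AUCs at small n; both
#' values are always reported.
#'
#' @param data Tibble of per-patient scores.
#' @param score,truth Column names (strings) of the numeric score and the
#'   logical/binary outcome.
#' @param smooth Fit the binormal smooth? (Both AUCs are reported when
#'   possible; degenerate class SDs disable the smooth.)
#' @return Object of class `ir_roc`: empirical points, binormal
#'   parameters, `auc_empirical`, `auc_smoothed`, class sizes.
#' @export
roc_auc_smoothed <- function(data, score = "score", truth = "recurrence",
                             smooth = TRUE) {
  s <- data[[score]]; y <- as.logical(data[[truth]])
  if (length(unique(y)) < 2) stop("both classes must be present")
  auc_e <- auc_empirical(s, y)
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- tibble::tibble(
    threshold = c(Inf, thr),
    sensitivity = vapply(c(Inf, thr), function(t) mean(s[y] >= t), 0),
    fpr = vapply(c(Inf, thr), function(t) mean(s[!y] >= t), 0))
  mu1 <- mean(s[y]); mu0 <- mean(s[!y])
  s1 <- sd(s[y]); s0 <- sd(s[!y])
  auc_s <- NA_real_; a <- NA_real_; b <- NA_real_
  if (smooth && is.finite(s1) && is.finite(s0) && s1 > 0 && s0 > 0) {
    a <- (mu1 - mu0) / s1
    b <- s0 / s1
    auc_s <- pnorm(a / sqrt(1 + b^2))
  }
  structure(list(points = pts, auc_empirical = auc_e, auc_smoothed = auc_s,
                 binormal_a = a, binormal_b = b,
                 n_case = sum(y), n_control = sum(!y)),
            class = "ir_roc")
}

#' @exportS3Method base::print
print.ir_roc <- function(x, ...) {
  cat(sprintf("<ir_roc> empirical AUC %.3f, smoothed (binormal) AUC %s (%d cases / %d controls)\n",
              x$auc_empirical,
              ifelse(is.na(x$auc_smoothed), "NA", sprintf("%.3f", x$auc_smoothed)),
              x$n_case, x$n_control))
  invisible(x)
}

#' @export
tidy.ir_roc <- function(x, ...) x$points

#' @export
glance.ir_roc <- function(x, ...) {
  tibble::tibble(auc_empirical = x$auc_empirical,
                 auc_smoothed = x$auc_smoothed,
                 n_case = x$n_case, n_control = x$n_control)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified (within-class) resampling of patients with replacement;
#' percentile interval. Deterministic for a fixed seed.
#'
#' @inheritParams roc_auc_smoothed
#' @param reps Bootstrap repetitions (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @param smoothed Use the binormal-smoothed AUC instead of the empirical?
#' @return Tibble: `estimate`, `lower`, `upper`, `level`, `reps`.
#' @export
bootstrap_auc_ci <- function(data, score = "score", truth = "recurrence",
                             reps = 2000, level = 0.95, seed = 1,
                             smoothed = FALSE) {
  s <- data[[score]]; y <- as.logical(data[[truth]])
  i1 <- which(y); i0 <- which(!y)
  stopifnot(length(i1) >= 1, length(i0) >= 1)
  stat <- function(sc, lb) {
    if (smoothed) {
      r <- roc_auc_smoothed(tibble::tibble(score = sc, truth = lb),
                            "score", "truth")
      if (!is.na(r$auc_smoothed)) r$auc_smoothed else r$auc_empirical
    } else auc_empirical(sc, lb)
  }
  est <- stat(s, y)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      b1 <- sample(i1, replace = TRUE)
      b0 <- sample(i0, replace = TRUE)
      stat(c(s[b1], s[b0]), c(rep(TRUE, length(b1)), rep(FALSE, length(b0))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(estimate = est, lower = ci[1], upper = ci[2],
                 level = level, reps = reps)
}

#' Paired bootstrap test for an AUC difference
#'
#' Resamples patients (stratified, paired across the two scores), computes
#' the AUC difference in each resample, and reports the two-sided p-value
#' for the difference being zero.
#'
#' @param data Tibble holding both score columns and the outcome.
#' @param score_a,score_b Column names of the two scores.
#' @param truth Outcome column name.
#' @param reps Bootstrap repetitions.
#' @param seed RNG seed.
#' @return Tibble: `auc_a`, `auc_b`, `difference`, `p_value`, `reps`.
#' @export
bootstrap_auc_difference <- function(data, score_a, score_b,
                                     truth = "recurrence", reps = 2000,
                                     seed = 1) {
  sa <- data[[score_a]]; sb <- data[[score_b]]
  y <- as.logical(data[[truth]])
  if (length(sa) != length(sb)) stop("score vectors differ in length")
  i1 <- which(y); i0 <- which(!y)
  auc_a <- auc_empirical(sa, y); auc_b <- auc_empirical(sb, y)
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      b1 <- sample(i1, replace = TRUE)
      b0 <- sample(i0, replace = TRUE)
      bl <- c(rep(TRUE, length(b1)), rep(FALSE, length(b0)))
      idx <- c(b1, b0)
      auc_empirical(sa[idx], bl) - auc_empirical(sb[idx], bl)
    }, numeric(1))
  })
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(p, 1)
  tibble::tibble(auc_a = auc_a, auc_b = auc_b,
                 difference = auc_a - auc_b, p_value = p, reps = reps)
}

#' Kolmogorov-Smirnov comparison of case and control score distributions
#'
#' Two-sample two-sided KS test of the scores of recurrent cases against
#' non-recurrent controls.
#'
#' @inheritParams roc_auc_smoothed
#' @return Tibble: `statistic` (D), `p_value`, class sizes.
#' @export
ks_compare <- function(data, score = "score", truth = "recurrence") {
  s <- data[[score]]; y <- as.logical(data[[truth]])
  stopifnot(sum(y) >= 1, sum(!y) >= 1)
  kt <- suppressWarnings(ks.test(s[y], s[!y]))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_case = sum(y), n_control = sum(!y))
}

#' Odds ratios for recurrence by score quartile
#'
#' Patients are assigned to quartiles by score order (stable, ties to the
#' lower quartile; quartile sizes differ by at most one). A logistic model
#' of recurrence on quartile indicators (lowest quartile as reference)
#' plus optional covariates yields Wald odds ratios and confidence
#' intervals; the trend test enters the quartile index as an ordinal
#' covariate. Separation triggers a weak-ridge refit with a warning
#' (interval estimates then unavailable).
#'
#' @inheritParams roc_auc_smoothed
#' @param covariates Character vector of covariate column names (entered
#'   linearly).
#' @param level Confidence level for the Wald intervals.
#' @return Tibble of class `ir_quartile_or` with one row per quartile:
#'   `quartile`, `n`, `cases`, `odds_ratio`, `ci_lower`, `ci_upper`,
#'   `p_wald`; the trend p-value is attached as attribute `p_trend` (also
#'   in `glance()`).
#' @export
quartile_odds_ratios <- function(data, score = "score", truth = "recurrence",
                                 covariates = NULL, level = 0.95) {
  s <- data[[score]]; y <- as.logical(data[[truth]])
  n <- length(s)
  r <- rank(s, ties.method = "first")
  q <- ceiling(r * 4 / n)
  if (min(table(q)) < 2) stop("fewer than 2 patients in a quartile")
  df <- tibble::tibble(.y = y, .q = factor(q, levels = 1:4))
  for (v in covariates) df[[v]] <- data[[v]]
  rhs <- paste(c(".q", covariates), collapse = " + ")
  fit <- glm(stats::as.formula(paste(".y ~", rhs)), family = binomial(),
             data = df)
  sm <- summary(fit)$coefficients
  zq <- qnorm(1 - (1 - level) / 2)
  separated <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8)
  rows <- purrr::map_dfr(1:4, function(k) {
    if (k == 1)
      return(tibble::tibble(quartile = 1L, n = sum(q == 1),
                            cases = sum(y[q == 1]), odds_ratio = 1,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            p_wald = NA_real_))
    term <- paste0(".q", k)
    est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
    tibble::tibble(quartile = k, n = sum(q == k), cases = sum(y[q == k]),
                   odds_ratio = exp(est),
                   ci_lower = if (separated) NA_real_ else exp(est - zq * se),
                   ci_upper = if (separated) NA_real_ else exp(est + zq * se),
                   p_wald = if (separated) NA_real_ else sm[term, "Pr(>|z|)"])
  })
  if (separated) {
    warning("separation in quartile logistic model; refitting with weak ridge")
    x <- stats::model.matrix(fit)[, -1, drop = FALSE]
    gfit <- glmnet::glmnet(x, as.numeric(y), family = "binomial", alpha = 0,
                           lambda = 1e-6, standardize = FALSE)
    co <- as.numeric(coef(gfit, s = 1e-6))[-1]
    names(co) <- colnames(x)
    for (k in 2:4) rows$odds_ratio[rows$quartile == k] <-
      exp(unname(co[paste0(".q", k)]))
  }
  df$.qnum <- q
  rhs_t <- paste(c(".qnum", covariates), collapse = " + ")
  tfit <- suppressWarnings(glm(stats::as.formula(paste(".y ~", rhs_t)),
                               family = binomial(), data = df))
  p_trend <- summary(tfit)$coefficients[".qnum", "Pr(>|z|)"]
  out <- rows
  attr(out, "p_trend") <- p_trend
  class(out) <- c("ir_quartile_or", class(out))
  out
}

#' @export
glance.ir_quartile_or <- function(x, ...) {
  tibble::tibble(p_trend = attr(x, "p_trend"),
                 or_highest = x$odds_ratio[x$quartile == 4])
}
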