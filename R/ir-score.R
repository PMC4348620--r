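#' Numeric code for pathologic stage
#' @param stage Character vector with values `"T2a"`, `"T2b"`, `"T3a"`,
#'   `"T3b"`.
#' @return Integer codes 1-4.
#' @export
stage_code <- function(stage) {
  code <- match(stage, c("T2a", "T2b", "T3a", "T3b"))
  if (any(is.na(code))) stop("unknown pathologic stage value")
  code
}

match_scaler <- function(training) {
  x <- cbind(age = training$age,
             gleason = training$gleason_sum,
             stage = stage_code(training$stage))
  centre <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  list(centre = centre, scale = scale_)
}

match_coords <- function(records, scaler) {
  x <- cbind(age = records$age,
             gleason = records$gleason_sum,
             stage = stage_code(records$stage))
  sweep(sweep(x, 2, scaler$centre), 2, scaler$scale, "/")
}

#' Find the most similar recurrent and non-recurrent training patients
#'
#' Similarity is the inverse Euclidean distance over z-score-standardized
#' age at prostatectomy, Gleason sum and pathologic stage code (T2a = 1 ..
#' T3b = 4); the scaler is fit on the training records. Ties are broken by
#' the lower patient id, with a warning.
#'
#' @param query One-row clinical tibble.
#' @param training Clinical tibble with a logical `recurrence` column
#'   containing at least one patient of each class.
#' @param scaler Optional precomputed scaler (internal use).
#' @return Tibble with two rows (`match_class` = `"recurrent"`,
#'   `"nonrecurrent"`) giving `patient_id` and `distance`.
#' @export
match_similar_patients <- function(query, training, scaler = NULL) {
  req <- c("age", "gleason_sum", "stage")
  if (any(vapply(req, function(v) is.null(query[[v]]) || is.na(query[[v]]),
                 logical(1))))
    stop("query is missing clinical variables (age, gleason_sum, stage)")
  if (sum(training$recurrence) < 1 || sum(!training$recurrence) < 1)
    stop("training set must contain both classes")
  scaler <- scaler %||% match_scaler(training)
  tx <- match_coords(training, scaler)
  qx <- match_coords(query, scaler)
  dist <- sqrt(rowSums(sweep(tx, 2, qx[1, ])^2))
  pick <- function(sel, label) {
    d <- dist[sel]; ids <- training$patient_id[sel]
    best <- min(d)
    cand <- ids[d <= best + 1e-12]
    if (length(cand) > 1)
      warning(sprintf("equidistant %s matches; taking lowest patient id", label))
    id <- sort(cand)[1]
    tibble::tibble(match_class = label, patient_id = id, distance = best)
  }
  dplyr::bind_rows(pick(training$recurrence, "recurrent"),
                   pick(!training$recurrence, "nonrecurrent"))
}

# Leave-one-out covariates: for each training patient, nPreference of their
# cores against the cores of the most similar recurrent / non-recurrent
# patient among the remaining training patients.
loo_covariates <- function(clinical, scores, d = 1) {
  score_sets <- split(scores$score, scores$patient_id)
  scaler <- match_scaler(clinical)
  purrr::map_dfr(seq_len(nrow(clinical)), function(i) {
    rest <- clinical[-i, , drop = FALSE]
    mm <- suppressWarnings(match_similar_patients(clinical[i, ], rest, scaler))
    s_q <- score_sets[[clinical$patient_id[i]]]
    s_rec <- score_sets[[mm$patient_id[mm$match_class == "recurrent"]]]
    s_non <- score_sets[[mm$patient_id[mm$match_class == "nonrecurrent"]]]
    tibble::tibble(patient_id = clinical$patient_id[i],
                   recurrence = clinical$recurrence[i],
                   npref_recurrent = npreference(s_q, s_rec, d),
                   npref_nonrecurrent = npreference(s_q, s_non, d))
  })
}

fit_logistic_ridge_fallback <- function(x, y) {
  fit <- suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || any(p > 1 - 1e-8) || any(p < 1e-8)
  if (!separated) return(list(coef = fit$coefficients, ridge = FALSE))
  warning("separation in logistic fit; applying weak ridge")
  gfit <- glmnet::glmnet(x, as.numeric(y), family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
  co <- as.numeric(coef(gfit, s = 1e-6))
  list(coef = setNames(co, c("(Intercept)", colnames(x))), ridge = TRUE)
}

#' Fit the logistic IR Score model
#'
#' Treats each training patient in turn as a held-out query against the
#' remaining training patients, computes the two normalized preference
#' covariates (against the most similar recurrent and non-recurrent
#' match), and fits a logistic regression of recurrence on them. Perfect
#' separation falls back to a weak ridge fit (with a warning). When the
#' covariates carry no information the model degenerates gracefully to the
#' class prevalence.
#'
#' @param clinical Training clinical tibble (>= 2 patients per class) with
#'   `patient_id`, `recurrence`, `age`, `gleason_sum`, `stage`.
#' @param scores Per-core score tibble (`patient_id`, `score`), e.g. from
#'   [pipeline_scores()].
#' @param d Rank exponent for the preference score.
#' @return Object of class `ir_score_model` holding the logistic
#'   coefficients, the training clinical records and core scores (needed to
#'   match and rank future queries), and the leave-one-out covariate table.
#' @export
fit_ir_score_model <- function(clinical, scores, d = 1) {
  if (sum(clinical$recurrence) < 2 || sum(!clinical$recurrence) < 2)
    stop("need at least two patients per class")
  cov <- loo_covariates(clinical, scores, d)
  x <- as.matrix(cov[, c("npref_recurrent", "npref_nonrecurrent")])
  y <- cov$recurrence
  if (all(apply(x, 2, function(v) max(v) - min(v)) < 1e-12)) {
    co <- c(`(Intercept)` = qlogis(mean(y)), npref_recurrent = 0,
            npref_nonrecurrent = 0)
    fit <- list(coef = co, ridge = FALSE)
  } else {
    fit <- fit_logistic_ridge_fallback(x, y)
  }
  structure(list(coef = fit$coef, ridge = fit$ridge, d = d,
                 covariates = cov, clinical = clinical, scores = scores),
            class = "ir_score_model")
}

#' @exportS3Method base::print
print.ir_score_model <- function(x, ...) {
  cat(sprintf("<ir_score_model> logit(PPR) = %.3f + %.3f nPref_rec + %.3f nPref_nonrec%s\n",
              x$coef[1], x$coef[2], x$coef[3],
              if (isTRUE(x$ridge)) " [ridge]" else ""))
  invisible(x)
}

#' @export
tidy.ir_score_model <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.ir_score_model <- function(x, ...) {
  tibble::tibble(n_patients = nrow(x$clinical),
                 prevalence = mean(x$clinical$recurrence),
                 ridge = isTRUE(x$ridge), d = x$d)
}

#' Predict the IR Score (probability of recurrence) for query patients
#'
#' For each query: find the most similar recurrent and non-recurrent
#' training patients by clinical lookup, compute the normalized preference
#' of the query's cores against each match's cores, and pass the two
#' covariates through the fitted logistic model.
#'
#' @param object A fitted `ir_score_model`.
#' @param query_clinical Clinical tibble of query patients.
#' @param query_scores Per-core score tibble (`patient_id`, `score`) for
#'   the query patients, on the same model scale as the training scores.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `npref_recurrent`,
#'   `npref_nonrecurrent`, `ir_score` (in (0, 1)).
#' @export
predict.ir_score_model <- function(object, query_clinical, query_scores, ...) {
  score_sets <- split(object$scores$score, object$scores$patient_id)
  q_sets <- split(query_scores$score, query_scores$patient_id)
  scaler <- match_scaler(object$clinical)
  purrr::map_dfr(seq_len(nrow(query_clinical)), function(i) {
    q <- query_clinical[i, , drop = FALSE]
    mm <- suppressWarnings(match_similar_patients(q, object$clinical, scaler))
    s_q <- q_sets[[q$patient_id]]
    if (is.null(s_q)) stop("no core scores for query patient ", q$patient_id)
    npr <- npreference(s_q, score_sets[[mm$patient_id[mm$match_class == "recurrent"]]],
                       object$d)
    npn <- npreference(s_q, score_sets[[mm$patient_id[mm$match_class == "nonrecurrent"]]],
                       object$d)
    eta <- object$coef[1] + object$coef[2] * npr + object$coef[3] * npn
    tibble::tibble(patient_id = q$patient_id,
                   npref_recurrent = npr, npref_nonrecurrent = npn,
                   ir_score = plogis(unname(eta)))
  })
}
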