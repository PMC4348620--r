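#' Configuration of the IR recurrence-prediction pipeline
#'
#' Bundles the tunable parameters of the full chain: equal-width
#' discretization, per-class FP-growth mining, two-stage discriminative
#' pattern selection, relevance/redundancy feature selection and the
#' linear Ranking-SVM.
#'
#' @param theta Minimum pattern support fraction (default 0.02).
#' @param n_bins Discretization bins per metric (default 20).
#' @param max_len Maximum pattern length mined (default 4).
#' @param m Number of discriminative patterns retained (default 100).
#' @param alpha1 Stage-1 significance level of the discriminative test.
#' @param k0 Stage-1 feature-selection target size.
#' @param refine Run the floating add/remove refinement (stage-2 feature
#'   selection)? Off by default; the mRMR ordering is always applied.
#' @param refine_folds,refine_max_iter Refinement inner-CV folds and sweep
#'   cap.
#' @param cost Ranking-SVM margin parameter C.
#' @param d Preference-score rank exponent.
#' @param cell_type Pixel population used by the pipeline (default
#'   `"stroma"`; use `NULL` for all pixels).
#' @param seed Seed for the seeded sub-steps (constraint subsampling,
#'   refinement folds).
#' @return A list of class `ir_pipeline_config`.
#' @export
pipeline_config <- function(theta = 0.02, n_bins = 20, max_len = 4,
                            m = 100, alpha1 = 0.05, k0 = 30,
                            refine = FALSE, refine_folds = 3,
                            refine_max_iter = 2, cost = 1, d = 1,
                            cell_type = "stroma", seed = 1) {
  structure(list(theta = theta, n_bins = n_bins, max_len = max_len, m = m,
                 alpha1 = alpha1, k0 = k0, refine = refine,
                 refine_folds = refine_folds,
                 refine_max_iter = refine_max_iter, cost = cost, d = d,
                 cell_type = cell_type, seed = as.integer(seed)),
            class = "ir_pipeline_config")
}

pipeline_pixels <- function(pixels, config) {
  if (!is.null(config$cell_type))
    pixels <- pixels[pixels$cell_type %in% config$cell_type, , drop = FALSE]
  if (nrow(pixels) == 0) stop("no pixels left after cell-type filtering")
  pixels
}

#' Fit the full IR pipeline on a training cohort
#'
#' Fits the discretizer on the training pixels, mines frequent patterns
#' separately in the recurrence and non-recurrence classes (FP-growth),
#' unions the two sets (per-class supports recorded; a pattern mined in
#' both classes is attributed to the class with higher support), applies
#' the two-stage discriminative test on per-subject pooled frequencies,
#' keeps the top `m` patterns, ranks their per-core frequency features by
#' relevance/redundancy (optionally refined), and trains the Ranking-SVM
#' on within-pair core ordering constraints.
#'
#' If the two-stage test leaves no survivors (typical of null data), the
#' top `m` patterns by stage-2 p-value are used instead, with a warning.
#'
#' @param pixels Training pixel tibble (`core_id`, `patient_id`,
#'   `cell_type`, `metric_*`).
#' @param clinical Training clinical tibble (`patient_id`, `pair_id`,
#'   `recurrence`, matching variables).
#' @param config A [pipeline_config()].
#' @return Object of class `ir_pipeline`: discretizer, union pattern set,
#'   retained patterns, selected features, ranking model, config.
#' @export
fit_ir_pipeline <- function(pixels, clinical, config = pipeline_config()) {
  px <- pipeline_pixels(pixels, config)
  is_case <- setNames(clinical$recurrence, clinical$patient_id)
  px_case <- is_case[px$patient_id]
  if (any(is.na(px_case))) stop("pixels reference patients missing from clinical")

  scheme <- fit_discretizer(px, n_bins = config$n_bins)
  disc <- metric_matrix(px)
  for (j in seq_along(scheme$metrics))
    disc[, scheme$metrics[j]] <- bin_values(disc[, scheme$metrics[j]],
                                            scheme$lo[j], scheme$width[j],
                                            scheme$n_bins, scheme$degenerate[j])
  storage.mode(disc) <- "integer"

  pat_case <- mine_frequent_patterns(disc[px_case, , drop = FALSE],
                                     theta = config$theta,
                                     max_len = config$max_len)
  pat_ctrl <- mine_frequent_patterns(disc[!px_case, , drop = FALSE],
                                     theta = config$theta,
                                     max_len = config$max_len)
  if (nrow(pat_case) + nrow(pat_ctrl) == 0)
    stop("no frequent patterns at theta = ", config$theta)
  pat_case$class <- "case"; pat_ctrl$class <- "control"
  union_pat <- dplyr::bind_rows(pat_case, pat_ctrl)
  dup <- duplicated(union_pat$pattern_id)
  both <- union_pat$pattern_id[dup]
  union_pat <- union_pat[!dup, , drop = FALSE]

  # per-core counts once; aggregate to per-class and per-subject quantities
  core_freq <- pattern_frequencies(disc, union_pat, px$core_id)
  core_patient <- px$patient_id[match(core_freq$group, px$core_id)]
  fmat <- as.matrix(core_freq[, union_pat$pattern_id, drop = FALSE])
  cmat <- fmat * core_freq$n_pixels
  subj <- rowsum(cmat, core_patient)
  subj_n <- rowsum(core_freq$n_pixels, core_patient)[, 1]
  subj_freq <- subj / subj_n
  # per-class pooled supports; settle source class of patterns mined in both
  case_rows <- is_case[rownames(subj_freq)]
  sup_case <- colSums(subj[case_rows, , drop = FALSE]) / sum(subj_n[case_rows])
  sup_ctrl <- colSums(subj[!case_rows, , drop = FALSE]) / sum(subj_n[!case_rows])
  union_pat$support_case <- unname(sup_case)
  union_pat$support_control <- unname(sup_ctrl)
  in_both <- union_pat$pattern_id %in% both
  union_pat$class[in_both] <- ifelse(
    union_pat$support_case[in_both] >= union_pat$support_control[in_both],
    "case", "control")

  freqs <- dplyr::bind_cols(
    tibble::tibble(group = rownames(subj_freq), n_pixels = unname(subj_n)),
    tibble::as_tibble(subj_freq))
  retained <- withCallingHandlers(
    select_discriminative_patterns(freqs, is_case, union_pat,
                                   m = config$m, alpha1 = config$alpha1),
    warning = function(w) {
      if (grepl("no discriminative patterns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (nrow(retained) == 0) {
    warning("two-stage selection empty; falling back to top-m by stage-2 p")
    retained <- select_discriminative_patterns(freqs, is_case, union_pat,
                                               m = config$m, alpha1 = 1 - 1e-12)
  }
  if (nrow(retained) == 0) stop("no usable patterns")

  feat <- dplyr::bind_cols(
    tibble::tibble(core_id = core_freq$group, n_pixels = core_freq$n_pixels),
    tibble::as_tibble(fmat[, retained$pattern_id, drop = FALSE]))
  feat$patient_id <- core_patient
  feat$recurrence <- unname(is_case[core_patient])
  feat$pair_id <- clinical$pair_id[match(core_patient, clinical$patient_id)]

  ranking <- rank_relevance_redundancy(feat, k0 = config$k0)
  selected <- ranking$feature
  if (isTRUE(config$refine)) {
    ref <- refine_subset(feat, selected, folds = config$refine_folds,
                         max_iter = config$refine_max_iter,
                         seed = config$seed, cost = config$cost)
    selected <- ref$selected
  }
  model <- train_ranking_svm(feat, features = selected, cost = config$cost,
                             seed = config$seed)
  train_scores <- tibble::tibble(core_id = feat$core_id,
                                 patient_id = feat$patient_id,
                                 n_pixels = feat$n_pixels,
                                 score = predict(model, feat))
  structure(list(scheme = scheme, patterns = union_pat, retained = retained,
                 ranking = ranking, selected = selected, model = model,
                 train_scores = train_scores, config = config),
            class = "ir_pipeline")
}

#' @exportS3Method base::print
print.ir_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<ir_pipeline> %d union patterns -> %d retained -> %d selected features; ",
                     "training pairwise accuracy %.3f\n"),
              nrow(x$patterns), nrow(x$retained), length(x$selected),
              x$model$training_accuracy))
  invisible(x)
}

#' Per-core ranking scores from a fitted pipeline
#'
#' Discretizes new pixels with the training scheme, computes the retained
#' pattern-frequency features per core, and scores each core with the
#' Ranking-SVM.
#'
#' @param fit An `ir_pipeline`.
#' @param pixels Pixel tibble for the cores to score; `NULL` returns the
#'   (cached) scores of the training cores.
#' @return Tibble `core_id`, `patient_id`, `n_pixels`, `score`.
#' @export
pipeline_scores <- function(fit, pixels = NULL) {
  if (is.null(pixels)) return(fit$train_scores)
  px <- pipeline_pixels(pixels, fit$config)
  disc <- discretize(px, fit$scheme)
  feat <- compute_pattern_features(disc, fit$retained)
  out <- tibble::tibble(core_id = feat$core_id,
                        patient_id = px$patient_id[match(feat$core_id, px$core_id)],
                        n_pixels = feat$n_pixels)
  out$score <- predict(fit$model, feat)
  out
}

#' Normalized preference between two patients under a fitted pipeline
#'
#' @param fit An `ir_pipeline`.
#' @param pixels Pixel tibble containing both patients' cores.
#' @param patient1,patient2 Patient ids.
#' @return An `ir_preference` (see [preference_score()]).
#' @export
npreference_patients <- function(fit, pixels, patient1, patient2) {
  sc <- pipeline_scores(fit, pixels[pixels$patient_id %in% c(patient1, patient2), ,
                                    drop = FALSE])
  preference_score(sc$score[sc$patient_id == patient1],
                   sc$score[sc$patient_id == patient2],
                   d = fit$config$d)
}
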