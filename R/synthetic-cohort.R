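#' Clinical marginal model for the synthetic cohort generator
#'
#' Distributions used to draw per-patient clinical variables. Defaults emulate
#' a mid-grade-dominant, recurrence-enriched radical-prostatectomy cohort:
#' age near 62 years, Gleason sum 7 dominant, mostly organ-confined stage,
#' log-normal PSA around 8-10 ng/mL.
#'
#' @param age_mean,age_sd Mean and SD (years) of age at prostatectomy.
#' @param age_match_window Maximum case-control age difference (years) when
#'   matching; controls are drawn uniformly within this window of their case.
#' @param gleason_probs Named probabilities for Gleason sum 6, 7, 8.
#' @param gleason7_major_prob Probability that a Gleason-7 tumor is 3+4
#'   (rather than 4+3).
#' @param stage_probs Named probabilities for pathologic stages
#'   T2a, T2b, T3a, T3b.
#' @param race_probs Named race probabilities.
#' @param psa_meanlog,psa_sdlog Log-normal parameters for PSA (ng/mL).
#' @param margin_prob,svi_prob,ece_prob,lni_prob Bernoulli probabilities for
#'   positive surgical margins, seminal vesicle invasion, extracapsular
#'   extension and lymph node invasion.
#' @param therapy_prob Probability of a neoadjuvant/adjuvant therapy record.
#' @param months_mean,months_sd Normal parameters (truncated at 1) for months
#'   to recurrence among cases.
#' @return A list of class `clinical_model`.
#' @export
clinical_model <- function(age_mean = 62, age_sd = 7, age_match_window = 3,
                           gleason_probs = c(`6` = 0.20, `7` = 0.70, `8` = 0.10),
                           gleason7_major_prob = 0.83,
                           stage_probs = c(T2a = 0.117, T2b = 0.550,
                                           T3a = 0.316, T3b = 0.017),
                           race_probs = c(White = 0.85, `African American` = 0.15),
                           psa_meanlog = 2.1, psa_sdlog = 0.7,
                           margin_prob = 0.35, svi_prob = 0.10,
                           ece_prob = 0.30, lni_prob = 0.03,
                           therapy_prob = 0.30,
                           months_mean = 38.6, months_sd = 29) {
  stopifnot(age_sd > 0, age_match_window >= 0,
            all(gleason_probs >= 0), all(stage_probs >= 0), all(race_probs >= 0))
  structure(list(
    age_mean = age_mean, age_sd = age_sd, age_match_window = age_match_window,
    gleason_probs = gleason_probs / sum(gleason_probs),
    gleason7_major_prob = gleason7_major_prob,
    stage_probs = stage_probs / sum(stage_probs),
    race_probs = race_probs / sum(race_probs),
    psa_meanlog = psa_meanlog, psa_sdlog = psa_sdlog,
    margin_prob = margin_prob, svi_prob = svi_prob,
    ece_prob = ece_prob, lni_prob = lni_prob,
    therapy_prob = therapy_prob,
    months_mean = months_mean, months_sd = months_sd
  ), class = "clinical_model")
}

#' Specify a pattern to plant in synthetic pixel data
#'
#' A planted pattern fixes the discretized values of a few metrics in a
#' Bernoulli-selected subset of stromal pixels, at a different rate in cases
#' than in controls, creating a known class-enriched co-occurrence signal.
#'
#' @param metrics Integer metric indices (1-based), all distinct.
#' @param bins Integer bin indices (0-based, one per metric) on the
#'   generator's nominal discretization grid.
#' @param enrich_case Fraction of case stromal pixels carrying the pattern,
#'   in (0, 1].
#' @param enrich_control Fraction of control stromal pixels carrying the
#'   pattern, in [0, 1].
#' @return A list of class `planted_pattern`.
#' @export
planted_pattern <- function(metrics, bins, enrich_case, enrich_control = 0) {
  metrics <- as.integer(metrics); bins <- as.integer(bins)
  if (length(metrics) != length(bins) || length(metrics) < 1)
    stop("`metrics` and `bins` must be non-empty and the same length")
  if (anyDuplicated(metrics)) stop("planted pattern uses a metric twice")
  if (enrich_case <= 0 || enrich_case > 1)
    stop("`enrich_case` must be in (0, 1]")
  if (enrich_control < 0 || enrich_control > 1)
    stop("`enrich_control` must be in [0, 1]")
  structure(list(metrics = metrics, bins = bins,
                 enrich_case = enrich_case, enrich_control = enrich_control),
            class = "planted_pattern")
}

#' Configuration for the synthetic matched case-control cohort
#'
#' @param n_pairs Number of matched case-control pairs (>= 1).
#' @param cores_per_patient Integer range `c(lo, hi)` of tissue cores per
#'   patient.
#' @param pixels_per_core Integer range `c(lo, hi)` of pixels per core.
#' @param n_metrics Number of spectral metrics k.
#' @param n_bins Bins per metric on the nominal discretization grid.
#' @param planted_patterns List of [planted_pattern()] specs.
#' @param noise_range Nominal range of the standard-normal baseline metric
#'   values; bin planting uses equal-width bins over this range.
#' @param clinical Clinical marginal model, see [clinical_model()].
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   cohort exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 60,
                          cores_per_patient = c(2L, 4L),
                          pixels_per_core = c(150L, 250L),
                          n_metrics = 12L,
                          n_bins = 20L,
                          planted_patterns = list(),
                          noise_range = c(-4.5, 4.5),
                          clinical = clinical_model(),
                          seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1) stop("`n_pairs` must be >= 1")
  cores_per_patient <- as.integer(round(cores_per_patient))
  pixels_per_core <- as.integer(round(pixels_per_core))
  if (length(cores_per_patient) == 1) cores_per_patient <- rep(cores_per_patient, 2)
  if (length(pixels_per_core) == 1) pixels_per_core <- rep(pixels_per_core, 2)
  if (pixels_per_core[1] < 1) stop("`pixels_per_core` must be >= 1")
  if (cores_per_patient[1] < 1) stop("`cores_per_patient` must be >= 1")
  n_metrics <- as.integer(n_metrics); n_bins <- as.integer(n_bins)
  stopifnot(n_metrics >= 1, n_bins >= 2, diff(noise_range) > 0)
  for (p in planted_patterns) {
    if (!inherits(p, "planted_pattern")) stop("planted_patterns must be planted_pattern() objects")
    if (any(p$metrics < 1 | p$metrics > n_metrics))
      stop("planted pattern references a metric outside 1..n_metrics")
    if (any(p$bins < 0 | p$bins >= n_bins))
      stop("planted pattern bin outside 0..n_bins-1")
  }
  structure(list(n_pairs = n_pairs, cores_per_patient = cores_per_patient,
                 pixels_per_core = pixels_per_core, n_metrics = n_metrics,
                 n_bins = n_bins, planted_patterns = planted_patterns,
                 noise_range = noise_range, clinical = clinical,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Nominal bin edges of the generator's discretization grid
#' @param config A [cohort_config()].
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
nominal_bin_edges <- function(config) {
  seq(config$noise_range[1], config$noise_range[2], length.out = config$n_bins + 1)
}

stage_levels <- c("T2a", "T2b", "T3a", "T3b")

draw_clinical_pairs <- function(config) {
  cm <- config$clinical
  n <- config$n_pairs
  draw_one <- function(recurrence) {
    gs <- as.integer(sample(names(cm$gleason_probs), 1, prob = cm$gleason_probs))
    if (gs == 7) {
      gp <- if (runif(1) < cm$gleason7_major_prob) 3L else 4L
    } else {
      gp <- as.integer(gs / 2)
    }
    tibble::tibble(
      age = rnorm(1, cm$age_mean, cm$age_sd),
      race = sample(names(cm$race_probs), 1, prob = cm$race_probs),
      gleason_primary = gp,
      gleason_secondary = gs - gp,
      gleason_sum = gs,
      stage = sample(stage_levels, 1, prob = cm$stage_probs),
      psa = rlnorm(1, cm$psa_meanlog, cm$psa_sdlog),
      margin = runif(1) < cm$margin_prob,
      svi = runif(1) < cm$svi_prob,
      ece = runif(1) < cm$ece_prob,
      lni = runif(1) < cm$lni_prob,
      therapy = runif(1) < cm$therapy_prob,
      recurrence = recurrence
    )
  }
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    case <- draw_one(TRUE)
    ctrl <- draw_one(FALSE)
    # exact matching on Gleason components, stage and race; age within window
    ctrl$gleason_primary <- case$gleason_primary
    ctrl$gleason_secondary <- case$gleason_secondary
    ctrl$gleason_sum <- case$gleason_sum
    ctrl$stage <- case$stage
    ctrl$race <- case$race
    ctrl$age <- case$age + runif(1, -cm$age_match_window, cm$age_match_window)
    case$months_to_recurrence <- max(1, rnorm(1, cm$months_mean, cm$months_sd))
    ctrl$months_to_recurrence <- NA_real_
    case$patient_id <- sprintf("P%03d", 2L * i - 1L)
    ctrl$patient_id <- sprintf("P%03d", 2L * i)
    case$pair_id <- ctrl$pair_id <- sprintf("PR%03d", i)
    rows[[2L * i - 1L]] <- case
    rows[[2L * i]] <- ctrl
  }
  dplyr::relocate(dplyr::bind_rows(rows), "patient_id", "pair_id")
}

# Generate one core's pixel grid, cell-type labels and baseline metrics.
core_pixels <- function(core_id, patient_id, n_px, n_metrics) {
  side <- ceiling(sqrt(n_px))
  grid <- expand.grid(x = 0:(side - 1), y = 0:(side - 1))[seq_len(n_px), , drop = FALSE]
  # epithelium occupies a central blob so that stromal adjacency is realistic
  frac_epi <- runif(1, 0.25, 0.50)
  ctr <- (side - 1) / 2
  d2 <- (grid$x - ctr)^2 + (grid$y - ctr)^2
  n_epi <- max(1L, round(frac_epi * n_px))
  cell_type <- rep("stroma", n_px)
  cell_type[order(d2)[seq_len(n_epi)]] <- "epithelium"
  metrics <- matrix(rnorm(n_px * n_metrics), nrow = n_px)
  list(core_id = core_id, patient_id = patient_id,
       x = grid$x, y = grid$y, cell_type = cell_type, metrics = metrics)
}

#' Generate a matched case-control cohort with planted pattern signal
#'
#' Draws per-patient clinical records (cases exactly matched to controls on
#' Gleason, stage and race and within the age window), per-core pixel grids
#' with epithelium/stroma labels, and standard-normal baseline metric values.
#' Planted patterns overwrite their metrics with the nominal bin's center
#' value plus sub-bin jitter in a Bernoulli-selected subset of stromal
#' pixels, at the configured per-class rates, so true pattern support is
#' known analytically.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ir_cohort` with elements `clinical` (tibble, one
#'   row per patient), `pixels` (tibble, one row per pixel with columns
#'   `core_id, patient_id, x, y, cell_type, metric_1..metric_k`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  clinical <- withr::with_seed(substream_seed(config$seed, "clinical"),
                               draw_clinical_pairs(config))
  k <- config$n_metrics
  cores <- withr::with_seed(substream_seed(config$seed, "pixels"), {
    out <- list()
    ci <- 0L
    for (pid in clinical$patient_id) {
      n_cores <- sample(seq(config$cores_per_patient[1], config$cores_per_patient[2]), 1)
      for (j in seq_len(n_cores)) {
        ci <- ci + 1L
        n_px <- sample(seq(config$pixels_per_core[1], config$pixels_per_core[2]), 1)
        out[[ci]] <- core_pixels(sprintf("%s_C%d", pid, j), pid, n_px, k)
      }
    }
    out
  })
  if (length(config$planted_patterns) > 0) {
    edges <- nominal_bin_edges(config)
    width <- diff(edges)[1]
    reps <- edges[-length(edges)] + width / 2
    is_case <- setNames(clinical$recurrence, clinical$patient_id)
    cores <- withr::with_seed(substream_seed(config$seed, "planting"), {
      for (ci in seq_along(cores)) {
        co <- cores[[ci]]
        stromal <- which(co$cell_type == "stroma")
        if (length(stromal) == 0) next
        for (p in config$planted_patterns) {
          rate <- if (is_case[[co$patient_id]]) p$enrich_case else p$enrich_control
          if (rate <= 0) next
          hit <- stromal[runif(length(stromal)) < rate]
          if (length(hit) == 0) next
          for (l in seq_along(p$metrics)) {
            centre <- reps[p$bins[l] + 1L]
            co$metrics[hit, p$metrics[l]] <-
              centre + runif(length(hit), -width / 8, width / 8)
          }
        }
        cores[[ci]] <- co
      }
      cores
    })
  }
  metric_names <- sprintf("metric_%d", seq_len(k))
  pixels <- purrr::map(cores, function(co) {
    colnames(co$metrics) <- metric_names
    m <- tibble::as_tibble(co$metrics)
    dplyr::bind_cols(
      tibble::tibble(core_id = co$core_id, patient_id = co$patient_id,
                     x = co$x, y = co$y, cell_type = co$cell_type), m)
  })
  pixels <- dplyr::bind_rows(pixels)
  structure(list(clinical = clinical, pixels = pixels, config = config),
            class = "ir_cohort")
}

#' Generate a null cohort: labels independent of all metric values
#'
#' Identical to [generate_cohort()] except that any planted patterns are
#' planted at the case rate in both classes, so the recurrence label carries
#' no information about the pixel data while marginal structure is kept.
#'
#' @inheritParams generate_cohort
#' @return An `ir_cohort`, see [generate_cohort()].
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$planted_patterns <- lapply(config$planted_patterns, function(p) {
    p$enrich_control <- p$enrich_case
    p
  })
  generate_cohort(config)
}

#' @exportS3Method base::print
print.ir_cohort <- function(x, ...) {
  cat(sprintf("<ir_cohort> %d patients (%d pairs), %d cores, %d pixels, %d metrics\n",
              nrow(x$clinical), x$config$n_pairs,
              dplyr::n_distinct(x$pixels$core_id), nrow(x$pixels),
              x$config$n_metrics))
  invisible(x)
}

#' Empirical planted-pattern match rates by class
#'
#' Computes, for each planted pattern, the fraction of stromal pixels in each
#' class whose metric values fall in the pattern's nominal bins. Used to
#' verify that planted enrichment is recovered.
#'
#' @param cohort An `ir_cohort` from [generate_cohort()].
#' @return Tibble with columns `pattern`, `class`, `n_pixels`, `match_rate`.
#' @export
planted_match_rates <- function(cohort) {
  config <- cohort$config
  if (length(config$planted_patterns) == 0)
    return(tibble::tibble(pattern = integer(), class = character(),
                          n_pixels = integer(), match_rate = double()))
  edges <- nominal_bin_edges(config)
  px <- dplyr::filter(cohort$pixels, .data$cell_type == "stroma")
  is_case <- cohort$clinical$recurrence[match(px$patient_id, cohort$clinical$patient_id)]
  purrr::imap_dfr(config$planted_patterns, function(p, idx) {
    match <- rep(TRUE, nrow(px))
    for (l in seq_along(p$metrics)) {
      v <- px[[sprintf("metric_%d", p$metrics[l])]]
      b <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE) - 1L, 0L),
                config$n_bins - 1L)
      match <- match & (b == p$bins[l])
    }
    tibble::tibble(pattern = idx,
                   class = c("case", "control"),
                   n_pixels = c(sum(is_case), sum(!is_case)),
                   match_rate = c(mean(match[is_case]), mean(match[!is_case])))
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `clinical.csv`, `pixels.csv` and a JSON `manifest.json` carrying
#' the generator configuration and seed.
#'
#' @param cohort An `ir_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(cohort$pixels, file.path(dir, "pixels.csv"))
  cfg <- cohort$config
  cfg$clinical <- unclass(cfg$clinical)
  cfg$planted_patterns <- lapply(cfg$planted_patterns, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `clinical.csv`, `pixels.csv`,
#'   `manifest.json`.
#' @return An `ir_cohort`.
#' @export
read_cohort <- function(dir) {
  clinical <- readr::read_csv(file.path(dir, "clinical.csv"),
                              show_col_types = FALSE)
  pixels <- readr::read_csv(file.path(dir, "pixels.csv"), show_col_types = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(clinical = clinical, pixels = pixels, config = manifest),
            class = "ir_cohort")
}
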