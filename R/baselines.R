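#' CAPRA-S point map
#'
#' Published post-surgical point assignments: up to 3 points each for PSA
#' and Gleason score, 2 for positive surgical margins and seminal vesicle
#' invasion, 1 for extracapsular extension and lymph node invasion; total
#' range 0-12. The map is an editable object so alternative cut-points can
#' be supplied.
#'
#' @param psa_cuts PSA (ng/mL) upper bounds for 0/1/2/3 points.
#' @param margin_points,svi_points,ece_points,lni_points Points for a
#'   positive finding.
#' @param category_cuts Lower bounds of the intermediate- and high-risk
#'   categories.
#' @return A list of class `capra_s_points`.
#' @export
capra_s_points <- function(psa_cuts = c(6, 10, 20),
                           margin_points = 2, svi_points = 2,
                           ece_points = 1, lni_points = 1,
                           category_cuts = c(3, 6)) {
  structure(list(psa_cuts = psa_cuts, margin_points = margin_points,
                 svi_points = svi_points, ece_points = ece_points,
                 lni_points = lni_points, category_cuts = category_cuts),
            class = "capra_s_points")
}

capra_gleason_points <- function(primary, secondary) {
  s <- primary + secondary
  dplyr::case_when(
    s <= 6 ~ 0L,
    primary == 3 & secondary == 4 ~ 1L,
    primary == 4 & secondary == 3 ~ 2L,
    s >= 8 ~ 3L,
    TRUE ~ NA_integer_)
}

capra_psa_points <- function(psa, cuts) {
  findInterval(psa, cuts, left.open = TRUE)
}

#' Compute the CAPRA-S score and risk category
#'
#' Sums the per-variable risk points (PSA, pathologic Gleason, surgical
#' margins, SVI, ECE, LNI). Scores 0-2 are low risk, 3-5 intermediate,
#' >= 6 high. Missing required variables raise an error (no silent
#' imputation).
#'
#' @param data Clinical tibble with columns `psa`, `gleason_primary`,
#'   `gleason_secondary`, `margin`, `svi`, `ece`, `lni`.
#' @param points A [capra_s_points()] map.
#' @return `data` with appended integer `capra_s` (0-12) and factor
#'   `capra_s_category` columns.
#' @export
capra_s_score <- function(data, points = capra_s_points()) {
  req <- c("psa", "gleason_primary", "gleason_secondary",
           "margin", "svi", "ece", "lni")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("missing clinical variables: ", paste(missing_cols, collapse = ", "))
  vals <- data[, req]
  if (any(!stats::complete.cases(vals)))
    stop("missing values in required CAPRA-S variables")
  if (any(data$psa < 0)) stop("PSA must be non-negative")
  score <- capra_psa_points(data$psa, points$psa_cuts) +
    capra_gleason_points(data$gleason_primary, data$gleason_secondary) +
    data$margin * points$margin_points +
    data$svi * points$svi_points +
    data$ece * points$ece_points +
    data$lni * points$lni_points
  if (any(is.na(score))) stop("Gleason combination outside the point map")
  data$capra_s <- as.integer(score)
  data$capra_s_category <- capra_s_category(data$capra_s, points)
  data
}

#' Risk category of a CAPRA-S score
#' @param score Integer scores in 0..12.
#' @param points A [capra_s_points()] map (for the category cut-points).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
capra_s_category <- function(score, points = capra_s_points()) {
  if (any(score < 0 | score > 12)) stop("CAPRA-S score out of range 0..12")
  cuts <- points$category_cuts
  factor(dplyr::case_when(score < cuts[1] ~ "low",
                          score < cuts[2] ~ "intermediate",
                          TRUE ~ "high"),
         levels = c("low", "intermediate", "high"))
}

#' Read / write a CAPRA-S point map as YAML
#' @param points A [capra_s_points()] map.
#' @param path YAML file path.
#' @return The map (read) or `path` invisibly (write).
#' @export
write_capra_s_points <- function(points, path) {
  yaml::write_yaml(unclass(points), path)
  invisible(path)
}

#' @rdname write_capra_s_points
#' @export
read_capra_s_points <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(capra_s_points, x)
}

#' Pluggable nomogram table for Kattan-style recurrence probabilities
#'
#' The published nomogram's Cox coefficients are proprietary and not
#' shipped; users supply a table mapping clinical variables to prognostic
#' points and total points to a recurrence-free probability.
#'
#' @param points Named list of functions, one per clinical variable; each
#'   maps the variable's value to prognostic points.
#' @param prob_map Data frame with columns `total_points` and
#'   `recurrence_prob` (interpolated linearly, clamped at the ends).
#' @return A list of class `kattan_table`.
#' @export
kattan_table <- function(points, prob_map) {
  stopifnot(is.list(points), length(points) > 0,
            all(c("total_points", "recurrence_prob") %in% names(prob_map)))
  structure(list(points = points, prob_map = prob_map), class = "kattan_table")
}

#' Kattan-style predicted probability of recurrence
#'
#' Sums the per-variable prognostic points from the supplied table and
#' interpolates the total into a probability of recurrence. Raises an
#' unsupported-operation error when no table is supplied (the published
#' Cox coefficients are not redistributable).
#'
#' @param data Clinical tibble containing the variables named by the
#'   table.
#' @param table A [kattan_table()].
#' @return `data` with an appended `kattan_ppr` column in (0, 1).
#' @export
kattan_ppr <- function(data, table = NULL) {
  if (is.null(table))
    stop("no Kattan nomogram table supplied; the published Cox ",
         "coefficients are not shipped - provide a kattan_table()")
  stopifnot(inherits(table, "kattan_table"))
  missing_cols <- setdiff(names(table$points), names(data))
  if (length(missing_cols))
    stop("missing clinical variables: ", paste(missing_cols, collapse = ", "))
  total <- rep(0, nrow(data))
  for (v in names(table$points))
    total <- total + vapply(data[[v]], table$points[[v]], numeric(1))
  data$kattan_ppr <- approx(table$prob_map$total_points,
                            table$prob_map$recurrence_prob,
                            xout = total, rule = 2)$y
  data
}

#' Weighted combination of the IR Score with an external score
#'
#' `C = (1 - x) * ir + x * external` with weight `x` in (0, 1]; both
#' inputs should be pre-normalized to `[0, 1]` (divide CAPRA-S by 12). A
#' convex combination: the result lies between the two scores.
#'
#' @param ir IR Scores in `[0, 1]`.
#' @param external External scores in `[0, 1]`.
#' @param x Weight of the external score, in (0, 1].
#' @return Numeric combined scores.
#' @export
combined_score <- function(ir, external, x) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x > 1)
    stop("`x` must be a single weight in (0, 1]")
  (1 - x) * ir + x * external
}
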