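#' Construct a pixel spectrum
#'
#' @param wavenumber Strictly monotone grid in cm^-1 within [720, 4000].
#' @param absorbance Finite absorbance values, same length.
#' @return A tibble of class `pixel_spectrum` with columns `wavenumber`,
#'   `absorbance`, ordered by increasing wavenumber.
#' @export
pixel_spectrum <- function(wavenumber, absorbance) {
  if (length(wavenumber) != length(absorbance))
    stop("`wavenumber` and `absorbance` must have the same length")
  d <- diff(wavenumber)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("`wavenumber` must be strictly monotone")
  if (any(wavenumber < 720 - 1e-8 | wavenumber > 4000 + 1e-8))
    stop("wavenumbers must lie within [720, 4000] cm^-1")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  ord <- order(wavenumber)
  structure(tibble::tibble(wavenumber = wavenumber[ord],
                           absorbance = absorbance[ord]),
            class = c("pixel_spectrum", class(tibble::tibble())))
}

#' Define a spectral metric
#'
#' A metric is a scalar summary of a pixel spectrum: absorbance at a peak,
#' a ratio of two peak absorbances, the area of a band, or the absorbance-
#' weighted center of gravity of a band. An optional two-point linear
#' baseline (anchored at two wavenumbers) is subtracted before evaluation.
#'
#' @param name Metric name (unique within a definition set).
#' @param kind One of `"peak_absorbance"`, `"peak_ratio"`, `"band_area"`,
#'   `"center_of_gravity"`.
#' @param peak Peak position in cm^-1 (peak_absorbance).
#' @param peaks Two peak positions in cm^-1, numerator first (peak_ratio).
#' @param band Band limits `c(lo, hi)` in cm^-1 (band_area,
#'   center_of_gravity).
#' @param baseline Optional two anchor wavenumbers for linear baseline
#'   subtraction.
#' @return A list of class `metric_definition`.
#' @export
metric_definition <- function(name,
                              kind = c("peak_absorbance", "peak_ratio",
                                       "band_area", "center_of_gravity"),
                              peak = NULL, peaks = NULL, band = NULL,
                              baseline = NULL) {
  kind <- match.arg(kind)
  if (kind == "peak_absorbance" && is.null(peak)) stop("`peak` required")
  if (kind == "peak_ratio" && (is.null(peaks) || length(peaks) != 2))
    stop("`peaks` must give two positions")
  if (kind %in% c("band_area", "center_of_gravity")) {
    if (is.null(band) || length(band) != 2) stop("`band` must be c(lo, hi)")
    if (band[1] >= band[2]) stop("band lower limit must be below upper limit")
  }
  if (!is.null(baseline) && length(baseline) != 2)
    stop("`baseline` must give two anchor wavenumbers")
  structure(list(name = name, kind = kind, peak = peak, peaks = peaks,
                 band = sort(band), baseline = baseline),
            class = "metric_definition")
}

#' Illustrative default spectral-metric definitions
#'
#' About twenty metrics over tissue-relevant infrared bands: peak
#' absorbances (e.g. the 1042 cm^-1 C-O stretch of oligosaccharides, amide
#' I/II, CH stretches, the broad 3000-3600 cm^-1 N-H/O-H region), peak
#' ratios, band areas and band centers of gravity. Any list of
#' [metric_definition()] objects may be supplied instead; the full
#' definition set used with real instruments is expected to be
#' configuration-driven.
#'
#' @return A named list of `metric_definition` objects.
#' @export
default_metric_definitions <- function() {
  defs <- list(
    metric_definition("abs_1042", "peak_absorbance", peak = 1042),
    metric_definition("abs_1080", "peak_absorbance", peak = 1080),
    metric_definition("abs_1236", "peak_absorbance", peak = 1236),
    metric_definition("abs_1394", "peak_absorbance", peak = 1394),
    metric_definition("abs_1454", "peak_absorbance", peak = 1454),
    metric_definition("abs_1545", "peak_absorbance", peak = 1545),
    metric_definition("abs_1655", "peak_absorbance", peak = 1655),
    metric_definition("abs_2852", "peak_absorbance", peak = 2852),
    metric_definition("abs_2924", "peak_absorbance", peak = 2924),
    metric_definition("abs_3290", "peak_absorbance", peak = 3290),
    metric_definition("ratio_1042_1545", "peak_ratio", peaks = c(1042, 1545)),
    metric_definition("ratio_1080_1545", "peak_ratio", peaks = c(1080, 1545)),
    metric_definition("ratio_1655_1545", "peak_ratio", peaks = c(1655, 1545)),
    metric_definition("ratio_2924_2852", "peak_ratio", peaks = c(2924, 2852)),
    metric_definition("area_990_1132", "band_area", band = c(990, 1132),
                      baseline = c(990, 1132)),
    metric_definition("area_1180_1300", "band_area", band = c(1180, 1300)),
    metric_definition("area_1360_1480", "band_area", band = c(1360, 1480)),
    metric_definition("area_3000_3600", "band_area", band = c(3000, 3600)),
    metric_definition("cog_990_1132", "center_of_gravity", band = c(990, 1132)),
    metric_definition("cog_1600_1700", "center_of_gravity", band = c(1600, 1700)),
    metric_definition("cog_3200_3400", "center_of_gravity", band = c(3200, 3400))
  )
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

nearest_index <- function(wn, pos) which.min(abs(wn - pos))

baseline_correct <- function(wn, ab, anchors) {
  if (is.null(anchors)) return(ab)
  i1 <- nearest_index(wn, anchors[1]); i2 <- nearest_index(wn, anchors[2])
  if (i1 == i2) return(ab - ab[i1])
  slope <- (ab[i2] - ab[i1]) / (wn[i2] - wn[i1])
  ab - (ab[i1] + slope * (wn - wn[i1]))
}

#' Evaluate one spectral metric on one spectrum
#'
#' Peak absorbance reads the (optionally baseline-corrected) absorbance at
#' the nearest grid point; peak ratio divides two peak absorbances; band
#' area integrates the band by the trapezoid rule; center of gravity is the
#' absorbance-weighted mean wavenumber over the band. A ratio or center of
#' gravity whose denominator magnitude is below `tol` returns `NA` (flagged
#' invalid).
#'
#' @param spectrum A [pixel_spectrum()] or data frame with `wavenumber` and
#'   `absorbance` columns.
#' @param definition A [metric_definition()].
#' @param tol Denominator tolerance for ratio-type metrics.
#' @return A single numeric value (`NA_real_` when flagged invalid).
#' @export
compute_metric <- function(spectrum, definition, tol = 1e-12) {
  stopifnot(inherits(definition, "metric_definition"))
  wn <- spectrum$wavenumber; ab <- spectrum$absorbance
  ord <- order(wn); wn <- wn[ord]; ab <- ab[ord]
  rng <- range(wn)
  check_pos <- function(p) {
    if (any(p < rng[1] - 1e-8 | p > rng[2] + 1e-8))
      stop(sprintf("position outside spectral range [%g, %g]", rng[1], rng[2]))
  }
  ab_c <- baseline_correct(wn, ab, definition$baseline)
  switch(definition$kind,
    peak_absorbance = {
      check_pos(definition$peak)
      ab_c[nearest_index(wn, definition$peak)]
    },
    peak_ratio = {
      check_pos(definition$peaks)
      num <- ab_c[nearest_index(wn, definition$peaks[1])]
      den <- ab_c[nearest_index(wn, definition$peaks[2])]
      if (abs(den) <= tol) NA_real_ else num / den
    },
    band_area = {
      check_pos(definition$band)
      sel <- wn >= definition$band[1] - 1e-8 & wn <= definition$band[2] + 1e-8
      w <- wn[sel]; a <- ab_c[sel]
      if (sum(sel) < 2) return(0)
      sum(diff(w) * (head(a, -1) + a[-1]) / 2)
    },
    center_of_gravity = {
      check_pos(definition$band)
      sel <- wn >= definition$band[1] - 1e-8 & wn <= definition$band[2] + 1e-8
      w <- wn[sel]; a <- ab_c[sel]
      s <- sum(a)
      if (abs(s) <= tol) NA_real_ else sum(w * a) / s
    })
}

#' Convert spectra to a per-pixel metric table
#'
#' @param spectra Long tibble with columns `pixel_id`, `wavenumber`,
#'   `absorbance`; all pixels must share one wavenumber grid.
#' @param defs List of [metric_definition()] objects.
#' @param invalid Policy for flagged-invalid values: `"drop"` removes the
#'   pixel (count reported via message), `"impute"` substitutes the column
#'   median.
#' @return Tibble with `pixel_id` and one column per metric, in `defs`
#'   order; no missing values remain.
#' @export
apply_metrics <- function(spectra, defs, invalid = c("drop", "impute")) {
  invalid <- match.arg(invalid)
  if (nrow(spectra) == 0 || length(defs) == 0) stop("empty input")
  split_px <- split(spectra, spectra$pixel_id)
  grids <- lapply(split_px, function(s) sort(s$wavenumber))
  g1 <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(g1) && all(abs(g - g1) < 1e-8),
                 logical(1))
  if (!all(same)) stop("all spectra must share a common wavenumber grid")
  vals <- vapply(split_px, function(s) {
    vapply(defs, function(d) compute_metric(s, d), numeric(1))
  }, numeric(length(defs)))
  vals <- matrix(vals, ncol = length(defs), byrow = TRUE,
                 dimnames = list(NULL, vapply(defs, `[[`, "", "name")))
  out <- dplyr::bind_cols(tibble::tibble(pixel_id = names(split_px)),
                          tibble::as_tibble(vals))
  bad <- !stats::complete.cases(out)
  if (any(bad)) {
    if (invalid == "drop") {
      message(sprintf("dropped %d pixel(s) with invalid metric values", sum(bad)))
      out <- out[!bad, , drop = FALSE]
    } else {
      for (nm in names(out)[-1]) {
        nas <- is.na(out[[nm]])
        if (any(nas)) out[[nm]][nas] <- median(out[[nm]], na.rm = TRUE)
      }
      message(sprintf("imputed invalid values in %d pixel(s)", sum(bad)))
    }
  }
  if (nrow(out) < 1) stop("no pixels remain after invalid-value handling")
  out
}

#' Write metric definitions to YAML or JSON
#' @param defs List of [metric_definition()] objects.
#' @param path Output path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_metric_definitions <- function(defs, path) {
  x <- lapply(unname(defs), function(d) Filter(Negate(is.null), unclass(d)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read metric definitions written by [write_metric_definitions()]
#' @param path YAML or JSON file.
#' @return Named list of `metric_definition` objects.
#' @export
read_metric_definitions <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  defs <- lapply(x, function(d) {
    metric_definition(d$name, d$kind, peak = d$peak,
                      peaks = unlist(d$peaks), band = unlist(d$band),
                      baseline = unlist(d$baseline))
  })
  setNames(defs, vapply(defs, `[[`, "", "name"))
}
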