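#' Read / write the per-pixel metric table
#'
#' Plain CSV with a header row and columns
#' `core_id, patient_id, x, y, cell_type, metric_*`; round-trips losslessly.
#'
#' @param path CSV file path.
#' @return `read_pixel_table()` returns a tibble; `write_pixel_table()`
#'   returns `path` invisibly.
#' @export
read_pixel_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_pixel_table
#' @param pixels Pixel tibble to write.
#' @export
write_pixel_table <- function(pixels, path) {
  readr::write_csv(pixels, path)
  invisible(path)
}

#' Read / write the per-patient clinical table
#' @param path CSV file path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_clinical_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_clinical_table
#' @param clinical Clinical tibble to write.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_csv(clinical, path)
  invisible(path)
}

#' Select stromal pixels adjacent to epithelium
#'
#' Returns the stroma-labeled pixels of one core whose grid distance to the
#' nearest epithelium pixel, scaled by the pixel pitch, is within
#' `radius_um`. With the default Chebyshev metric, 6.25 um pitch and a 50 um
#' radius this is an 8-pixel neighborhood (a pixel exactly 8 pixels away, at
#' 50.0 um, is included).
#'
#' @param mask Tibble with columns `x`, `y`, `cell_type` (values
#'   `"epithelium"`, `"stroma"`, `"other"`) for a single core.
#' @param radius_um Adjacency radius in micrometres.
#' @param pitch_um Pixel pitch in micrometres.
#' @param distance `"chebyshev"` (default; morphological-dilation
#'   equivalent) or `"euclidean"`.
#' @return The subset of `mask` rows that are adjacent stroma (possibly
#'   empty, with a warning when the core has no epithelium).
#' @export
select_adjacent_stroma <- function(mask, radius_um = 50, pitch_um = 6.25,
                                   distance = c("chebyshev", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(nrow(mask) > 0, pitch_um > 0)
  epi <- mask[mask$cell_type == "epithelium", , drop = FALSE]
  str <- mask[mask$cell_type == "stroma", , drop = FALSE]
  if (nrow(epi) == 0) {
    warning("core has no epithelium pixels; returning empty selection")
    return(str[0, , drop = FALSE])
  }
  if (nrow(str) == 0) return(str)
  dx <- abs(outer(str$x, epi$x, "-"))
  dy <- abs(outer(str$y, epi$y, "-"))
  d <- if (distance == "chebyshev") pmax(dx, dy) else sqrt(dx^2 + dy^2)
  dmin <- apply(d, 1, min) * pitch_um
  str[dmin <= radius_um + 1e-9, , drop = FALSE]
}

#' Core- and patient-level eligibility filtering
#'
#' A core is eligible when its epithelium fraction is at least
#' `min_epithelium_fraction` (cores under 10% malignant epithelium are
#' omitted by default) and it has at least one adjacent stromal pixel. A
#' patient is eligible with at least `min_cores` eligible cores.
#'
#' @param pixels Pixel tibble (`core_id, patient_id, x, y, cell_type, ...`).
#' @param min_epithelium_fraction Minimum epithelium fraction per core.
#' @param min_cores Minimum eligible cores per patient.
#' @param radius_um,pitch_um,distance Passed to [select_adjacent_stroma()].
#' @return Tibble with one row per core: pixel counts, epithelium fraction,
#'   adjacent-stroma count, `core_eligible`, an exclusion `reason`
#'   (`NA` when eligible) and `patient_eligible`.
#' @export
filter_eligible <- function(pixels, min_epithelium_fraction = 0.10,
                            min_cores = 2, radius_um = 50, pitch_um = 6.25,
                            distance = "chebyshev") {
  cores <- pixels |>
    dplyr::group_by(.data$core_id, .data$patient_id) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      epithelium_fraction = mean(.data$cell_type == "epithelium"),
      .groups = "drop")
  adj <- vapply(cores$core_id, function(cid) {
    m <- pixels[pixels$core_id == cid, c("x", "y", "cell_type")]
    if (!any(m$cell_type == "epithelium")) return(0L)
    nrow(select_adjacent_stroma(m, radius_um, pitch_um, distance))
  }, integer(1))
  cores$n_adjacent_stroma <- adj
  cores$core_eligible <- cores$epithelium_fraction >= min_epithelium_fraction &
    cores$n_adjacent_stroma > 0
  cores$reason <- dplyr::case_when(
    cores$epithelium_fraction < min_epithelium_fraction ~ "insufficient epithelium",
    cores$n_adjacent_stroma == 0 ~ "no adjacent stroma",
    TRUE ~ NA_character_)
  cores <- cores |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(patient_eligible = sum(.data$core_eligible) >= min_cores) |>
    dplyr::ungroup()
  cores
}

#' Pixels of eligible cores of eligible patients
#'
#' Convenience filter applying [filter_eligible()] and returning the pixel
#' rows that survive.
#'
#' @inheritParams filter_eligible
#' @return Pixel tibble restricted to eligible cores of eligible patients.
#' @export
filter_eligible_pixels <- function(pixels, min_epithelium_fraction = 0.10,
                                   min_cores = 2, radius_um = 50,
                                   pitch_um = 6.25, distance = "chebyshev") {
  elig <- filter_eligible(pixels, min_epithelium_fraction, min_cores,
                          radius_um, pitch_um, distance)
  keep <- elig$core_id[elig$core_eligible & elig$patient_eligible]
  pixels[pixels$core_id %in% keep, , drop = FALSE]
}
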