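flat_spectrum <- function() {
  wn <- seq(1000, 1100, by = 2)
  pixel_spectrum(wn, rep(1, length(wn)))
}

test_that("center of gravity of a flat band is the band midpoint", {
  d <- metric_definition("cog", "center_of_gravity", band = c(1000, 1100))
  expect_equal(compute_metric(flat_spectrum(), d), 1050)
})

test_that("peak ratio divides the two nearest-point absorbances", {
  wn <- seq(900, 1200, by = 4)
  ab <- rep(0.1, length(wn))
  ab[which.min(abs(wn - 1000))] <- 0.8
  ab[which.min(abs(wn - 1100))] <- 0.4
  sp <- pixel_spectrum(wn, ab)
  d <- metric_definition("r", "peak_ratio", peaks = c(1000, 1100))
  expect_equal(compute_metric(sp, d), 2.0)
  # denominator at zero is flagged invalid
  ab[which.min(abs(wn - 1100))] <- 0
  d0 <- metric_definition("r0", "peak_ratio", peaks = c(1000, 1100))
  expect_true(is.na(compute_metric(pixel_spectrum(wn, ab), d0)))
})

test_that("band area matches an explicit trapezoid-summation oracle", {
  wn <- seq(1000, 1090, by = 2)
  ab <- pmax(0, 1 - abs(wn - 1042) / 20)
  sp <- pixel_spectrum(wn, ab)
  d <- metric_definition("a", "band_area", band = c(1022, 1062))
  sel <- wn >= 1022 & wn <= 1062
  expect_equal(compute_metric(sp, d), trapz_oracle(wn[sel], ab[sel]))
})

test_that("positions outside the spectral range raise errors", {
  d <- metric_definition("p", "peak_absorbance", peak = 1500)
  expect_error(compute_metric(flat_spectrum(), d), "outside")
  expect_error(pixel_spectrum(c(500, 600), c(1, 1)), "720")
  expect_error(pixel_spectrum(c(1000, 1000), c(1, 1)), "monotone")
})

test_that("apply_metrics builds an n x k table in definition order", {
  wn <- seq(1000, 1100, by = 2)
  mk <- function(scale) tibble::tibble(wavenumber = wn, absorbance = scale * (1 + (wn - 1000) / 100))
  spectra <- dplyr::bind_rows(
    dplyr::mutate(mk(1), pixel_id = "px1"),
    dplyr::mutate(mk(2), pixel_id = "px2"),
    dplyr::mutate(mk(1), pixel_id = "px3"))
  defs <- list(metric_definition("a1042", "peak_absorbance", peak = 1042),
               metric_definition("cog", "center_of_gravity", band = c(1000, 1100)))
  out <- apply_metrics(spectra, defs)
  expect_equal(dim(out), c(3L, 3L))
  expect_equal(names(out), c("pixel_id", "a1042", "cog"))
  # identical spectra give identical rows
  expect_equal(out$a1042[out$pixel_id == "px1"], out$a1042[out$pixel_id == "px3"])
})

test_that("invalid metric values follow the drop policy", {
  wn <- seq(1000, 1100, by = 2)
  good <- tibble::tibble(pixel_id = "ok", wavenumber = wn,
                         absorbance = 1 + (wn - 1000) / 100)
  zero <- tibble::tibble(pixel_id = "zz", wavenumber = wn, absorbance = 0)
  defs <- list(metric_definition("cog", "center_of_gravity", band = c(1000, 1100)))
  expect_message(out <- apply_metrics(dplyr::bind_rows(good, zero), defs),
                 "dropped 1")
  expect_equal(out$pixel_id, "ok")
  expect_message(imp <- apply_metrics(dplyr::bind_rows(good, zero), defs,
                                      invalid = "impute"), "imputed")
  expect_equal(nrow(imp), 2)
  expect_false(anyNA(imp))
})

test_that("metric definitions round-trip through YAML and JSON", {
  defs <- default_metric_definitions()
  for (ext in c("yml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_metric_definitions(defs, path)
    back <- read_metric_definitions(path)
    expect_equal(names(back), names(defs))
    expect_equal(back[["area_990_1132"]]$band, defs[["area_990_1132"]]$band)
    expect_equal(back[["ratio_2924_2852"]]$peaks, defs[["ratio_2924_2852"]]$peaks)
  }
})

test_that("stromal adjacency uses the Chebyshev 8-pixel rule at 50 um", {
  mk_mask <- function(dx) tibble::tibble(
    x = c(0L, dx), y = c(0L, 0L),
    cell_type = c("epithelium", "stroma"))
  expect_equal(nrow(select_adjacent_stroma(mk_mask(8))), 1)   # 50.0 um
  expect_equal(nrow(select_adjacent_stroma(mk_mask(9))), 0)   # 56.25 um
  all_epi <- tibble::tibble(x = 0:3, y = rep(0L, 4),
                            cell_type = rep("epithelium", 4))
  expect_equal(nrow(select_adjacent_stroma(all_epi)), 0)
  no_epi <- tibble::tibble(x = 0:3, y = rep(0L, 4),
                           cell_type = rep("stroma", 4))
  expect_warning(out <- select_adjacent_stroma(no_epi), "no epithelium")
  expect_equal(nrow(out), 0)
})

test_that("adjacency selection is monotone in the radius", {
  coh <- tiny_cohort(n_pairs = 2, seed = 3)
  m <- coh$pixels[coh$pixels$core_id == coh$pixels$core_id[1],
                  c("x", "y", "cell_type")]
  small <- select_adjacent_stroma(m, radius_um = 25)
  large <- select_adjacent_stroma(m, radius_um = 50)
  key <- function(d) paste(d$x, d$y)
  expect_true(all(key(small) %in% key(large)))
})

test_that("eligibility applies the 10% epithelium and two-core rules", {
  mk_core <- function(core, patient, n_epi, n_str) {
    n <- n_epi + n_str
    tibble::tibble(core_id = core, patient_id = patient,
                   x = seq_len(n) - 1L, y = 0L,
                   cell_type = c(rep("epithelium", n_epi), rep("stroma", n_str)))
  }
  px <- dplyr::bind_rows(
    mk_core("c1", "p1", 9, 91),    # 9% epithelium: excluded
    mk_core("c2", "p1", 10, 90),   # exactly 10%: included
    mk_core("c3", "p1", 30, 70),
    mk_core("c4", "p2", 30, 70))   # p2 has only one eligible core
  el <- filter_eligible(px)
  expect_false(el$core_eligible[el$core_id == "c1"])
  expect_equal(el$reason[el$core_id == "c1"], "insufficient epithelium")
  expect_true(el$core_eligible[el$core_id == "c2"])
  expect_true(all(el$patient_eligible[el$patient_id == "p1"]))
  expect_false(any(el$patient_eligible[el$patient_id == "p2"]))
  kept <- filter_eligible_pixels(px)
  expect_setequal(unique(kept$core_id), c("c2", "c3"))
  expect_true(all(kept$core_id %in% px$core_id))
})

test_that("pixel and clinical tables round-trip losslessly", {
  coh <- tiny_cohort(n_pairs = 2, seed = 4)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_pixel_table(coh$pixels, fp)
  expect_equal(as.data.frame(read_pixel_table(fp)), as.data.frame(coh$pixels))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_clinical_table(coh$clinical, fc)
  expect_equal(as.data.frame(read_clinical_table(fc)),
               as.data.frame(coh$clinical))
})
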