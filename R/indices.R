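# Composite laboratory / anthropometric indices consumed by the deficit
# score and the survival models.

#' Add derived prognostic indices to a cohort
#'
#' Computes, per patient:
#' * `nlr`  — neutrophil-to-lymphocyte ratio, neutrophils / lymphocytes;
#' * `plr`  — platelet-to-lymphocyte ratio, platelets / lymphocytes;
#' * `sii`  — systemic immune-inflammation index, PLR x neutrophils
#'   (computed at full precision, algebraically
#'   platelets x neutrophils / lymphocytes);
#' * `pni`  — prognostic nutrition index, here defined as
#'   albumin x lymphocytes (set `pni_convention = "onodera"` for the
#'   conventional 10 x albumin + 5 x lymphocytes form);
#' * `bmi`  — weight_kg / (height_cm / 100)^2, in kg/m^2.
#'
#' Any index with a missing input is itself missing; indices are never
#' emitted as `NaN` or infinite. A zero or negative lymphocyte count is a
#' per-patient computation error (cohort validation already excludes it for
#' file-based cohorts).
#'
#' @param data A cohort data frame carrying the laboratory columns
#'   (`neutrophils`, `lymphocytes`, `platelets`, `albumin`) plus `weight_kg`
#'   and `height_cm`.
#' @param pni_convention `"product"` (albumin x lymphocytes, the default) or
#'   `"onodera"` (10 x albumin + 5 x lymphocytes, counts in k/uL).
#' @return The input tibble with columns `nlr`, `plr`, `sii`, `pni`, `bmi`
#'   appended (existing columns of those names are overwritten).
#' @export
#' @examples
#' tibble::tibble(neutrophils = 4, lymphocytes = 2, platelets = 200,
#'                albumin = 3.5, weight_kg = 70, height_cm = 175) |>
#'   add_indices()
add_indices <- function(data, pni_convention = c("product", "onodera")) {
  pni_convention <- match.arg(pni_convention)
  need <- c("neutrophils", "lymphocytes", "platelets", "albumin",
            "weight_kg", "height_cm")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("add_indices requires column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "dasi_schema_error")
  }
  bad <- which(!is.na(data$lymphocytes) & data$lymphocytes <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive lymphocyte count at row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 "; ratios would be undefined"),
          class = "dasi_computation_error")
  }
  bad_h <- which(!is.na(data$height_cm) & data$height_cm <= 0)
  if (length(bad_h) > 0) {
    abort(paste0("non-positive height at row(s) ",
                 paste(head(bad_h, 5), collapse = ", ")),
          class = "dasi_computation_error")
  }
  pni <- if (pni_convention == "product") {
    data$albumin * data$lymphocytes
  } else {
    10 * data$albumin + 5 * data$lymphocytes
  }
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    nlr = .data$neutrophils / .data$lymphocytes,
    plr = .data$platelets / .data$lymphocytes,
    sii = .data$platelets * .data$neutrophils / .data$lymphocytes,
    pni = pni,
    bmi = .data$weight_kg / (.data$height_cm / 100)^2
  )
  stopifnot(!any(is.nan(out$nlr) & !is.na(data$neutrophils) & !is.na(data$lymphocytes)))
  out
}

#' Albumin-corrected calcium
#'
#' Helper for cohorts that supply only total serum calcium:
#' corrected = measured + 0.8 x (4.0 - albumin). Cohorts following the
#' standard column dictionary carry `corrected_calcium` directly as a
#' collected field and do not need this.
#'
#' @param total_calcium Measured total serum calcium, mg/dL.
#' @param albumin Serum albumin, g/dL.
#' @return Corrected calcium, mg/dL; missing where either input is missing.
#' @export
correct_calcium <- function(total_calcium, albumin) {
  total_calcium + 0.8 * (4.0 - albumin)
}
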