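# Patient-level cohort data model: schema, validated delimited-text IO, and
# the categorical grouping rules applied before analysis.

# Column dictionary for a cohort file. Booleans are stored 0/1 on disk.
COHORT_LOGICAL <- c("readmitted_30d", "metastasis", "event")
COHORT_ENUMS <- list(
  sex            = c("female", "male"),
  marital_status = c("single", "divorced", "widowed", "married"),
  language       = c("english", "not_english"),
  race           = c("white", "not_white"),
  fall_risk      = c("low", "moderate", "high", "universal")
)
COHORT_LABS <- c(
  "wbc", "hemoglobin", "platelets", "neutrophils", "lymphocytes",
  "sodium", "creatinine", "corrected_calcium", "albumin"
)
COHORT_NUMERIC <- c(
  "age", "ecog_ps", "karnofsky", "healthcare_visits_6mo",
  "length_of_index_admission", "weight_kg", "height_cm",
  COHORT_LABS, "n_medications", "survival_time"
)
COHORT_CHARACTER <- c("patient_id", "chief_complaint", "cancer_type_raw")

#' Cohort column dictionary
#'
#' Names and types of the columns a cohort table must carry: one row per
#' admitted patient, with demographics, admission metadata, the laboratory
#' panel drawn at the index admission, the 30-day readmission flag, and the
#' survival outcome (`survival_time` in days from index admission,
#' `event` = death observed).
#'
#' @return A tibble with columns `column`, `type` and `allowed` (allowed
#'   levels for enumerated columns, `NA` otherwise).
#' @export
#' @examples
#' cohort_columns()
cohort_columns <- function() {
  cols <- c(COHORT_CHARACTER[1], "readmitted_30d", "sex", "age",
            "marital_status", "language", "race", "fall_risk", "ecog_ps",
            "karnofsky", "healthcare_visits_6mo", "length_of_index_admission",
            "chief_complaint", "cancer_type_raw", "metastasis",
            "weight_kg", "height_cm", COHORT_LABS, "n_medications",
            "survival_time", "event")
  tibble::tibble(
    column = cols,
    type = dplyr::case_when(
      cols %in% COHORT_LOGICAL ~ "logical",
      cols %in% COHORT_NUMERIC ~ "numeric",
      TRUE ~ "character"
    ),
    allowed = purrr::map_chr(cols, function(cl) {
      if (cl %in% names(COHORT_ENUMS)) paste(COHORT_ENUMS[[cl]], collapse = "|")
      else NA_character_
    })
  )
}

#' Validate a cohort table
#'
#' Checks a cohort data frame against the column dictionary and the domain
#' invariants: unique patient identifiers, positive survival times, a
#' non-missing event indicator, ECOG performance status in 0-4, Karnofsky
#' score a multiple of 10 in 0-100, strictly positive laboratory values, and
#' enumerated columns restricted to their allowed levels.
#'
#' @param data A data frame with the columns of [cohort_columns()].
#' @return The validated data, invisibly coerced to a tibble; errors describe
#'   the offending column and rows.
#' @export
validate_cohort <- function(data) {
  dict <- cohort_columns()
  missing_cols <- setdiff(dict$column, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "dasi_schema_error")
  }
  data <- tibble::as_tibble(data)

  if (anyDuplicated(data$patient_id) > 0) {
    dups <- unique(data$patient_id[duplicated(data$patient_id)])
    abort(paste0("duplicate patient_id: ", paste(head(dups, 5), collapse = ", ")),
          class = "dasi_validation_error")
  }

  fail <- function(col, bad_rows, why) {
    abort(sprintf("invalid %s (%s) at row(s) %s", col, why,
                  paste(head(bad_rows, 5), collapse = ", ")),
          class = "dasi_validation_error")
  }
  check <- function(col, ok, why) {
    bad <- which(!ok & !is.na(data[[col]]))
    if (length(bad) > 0) fail(col, bad, why)
  }

  if (anyNA(data$survival_time) || anyNA(data$event)) {
    fail("survival_time/event",
         which(is.na(data$survival_time) | is.na(data$event)),
         "outcome may not be missing")
  }
  check("survival_time", data$survival_time > 0, "must be > 0")
  check("ecog_ps", data$ecog_ps %in% 0:4, "must be in 0-4")
  check("karnofsky", data$karnofsky %in% seq(0, 100, 10),
        "must be a multiple of 10 in 0-100")
  for (lab in COHORT_LABS) check(lab, data[[lab]] > 0, "must be > 0")
  for (col in c("age", "healthcare_visits_6mo", "length_of_index_admission",
                "n_medications")) {
    check(col, data[[col]] >= 0, "must be >= 0")
  }
  for (col in c("weight_kg", "height_cm")) check(col, data[[col]] > 0, "must be > 0")
  for (col in names(COHORT_ENUMS)) {
    check(col, data[[col]] %in% COHORT_ENUMS[[col]],
          paste0("must be one of ", paste(COHORT_ENUMS[[col]], collapse = "/")))
  }
  invisible(data)
}

#' Read a cohort table from delimited text
#'
#' Reads a UTF-8 delimited cohort file (comma by default, tab accepted) with
#' the header documented in [cohort_columns()], maps empty cells and the
#' missing-value sentinel to `NA`, decodes 0/1 booleans, and validates every
#' domain invariant before returning.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param na Missing-value sentinels; empty cells are always missing.
#' @return A validated cohort tibble, one row per patient, with a
#'   `provenance` attribute recording the source path.
#' @export
read_cohort <- function(path, delim = ",", na = c("", "NA")) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "dasi_io_error")
  }
  dict <- cohort_columns()
  # parse only the schema columns actually present; absent columns are a
  # schema error reported after the read, not a parser warning
  header <- strsplit(readr::read_lines(path, n_max = 1), delim,
                     fixed = TRUE)[[1]]
  dict_present <- dict[dict$column %in% header, , drop = FALSE]
  spec <- do.call(readr::cols, c(
    setNames(lapply(dict_present$type, function(t) {
      switch(t, numeric = readr::col_double(),
             logical = readr::col_double(),  # 0/1 on disk
             readr::col_character())
    }), dict_present$column),
    list(.default = readr::col_character())
  ))
  # readr's advisory warning is redundant: problems() is converted to a
  # typed parse error right below
  raw <- suppressWarnings(
    readr::read_delim(path, delim = delim, na = unique(c("", na)),
                      col_types = spec, progress = FALSE,
                      show_col_types = FALSE)
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf("cohort parse error at row %d, column %s: expected %s, got '%s'",
                  p$row, names(raw)[p$col] %||% p$col, p$expected, p$actual),
          class = "dasi_parse_error")
  }
  missing_cols <- setdiff(dict$column, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "dasi_schema_error")
  }
  for (col in COHORT_LOGICAL) {
    v <- raw[[col]]
    if (any(!v %in% c(0, 1) & !is.na(v))) {
      abort(paste0("column ", col, " must be encoded 0/1"),
            class = "dasi_parse_error")
    }
    raw[[col]] <- as.logical(v)
  }
  out <- validate_cohort(raw)
  attr(out, "provenance") <- normalizePath(path)
  out
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: booleans are encoded 0/1, missing values as
#' `"NA"`. `read_cohort(write_cohort(x, path))` is the identity on valid
#' cohorts.
#'
#' @param data A cohort data frame (validated before writing).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, delim = ",") {
  data <- validate_cohort(data)
  out <- data
  for (col in COHORT_LOGICAL) out[[col]] <- as.integer(out[[col]])
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

# -- categorical grouping rules ----------------------------------------------

#' Default chief-complaint grouping lexicon
#'
#' Keyword table mapping free-text reasons for admission to the eight
#' analysis categories (pain, neurologic, dyspnea, chemotherapy side effect,
#' abnormal findings, dehydration, fever, other). Matching is
#' case-insensitive substring search, categories tried in the listed order;
#' anything unmatched falls through to `other`. The table is data, not code:
#' supply your own via the `lexicon` argument of [group_admission_reason()]
#' or a YAML file read with [read_lexicon()].
#'
#' @return Named list of character keyword vectors.
#' @export
default_reason_lexicon <- function() {
  list(
    pain             = c("pain"),
    neurologic       = c("syncope", "dizziness", "headache", "diplopia",
                         "ataxia", "neurolog", "seizure"),
    dyspnea          = c("shortness of breath", "dyspnea", "hypoxia", "breath"),
    chemo_side_effect = c("nausea", "vomiting", "diarrhea", "chemotherapy"),
    abnormal_findings = c("abnormal", "ekg", "electrocardiogram", "lab value",
                          "laboratory", "imaging", "radiograph"),
    dehydration      = c("dehydrat"),
    fever            = c("fever", "febrile", "neutropenic fever")
  )
}

#' Read a grouping lexicon from YAML
#'
#' @param path YAML file mapping category name to a list of keywords.
#' @return Named list of character keyword vectors.
#' @export
read_lexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  lapply(lex, as.character)
}

REASON_LEVELS <- c("pain", "neurologic", "dyspnea", "chemo_side_effect",
                   "abnormal_findings", "dehydration", "fever", "other")

#' Group free-text admission reasons into analysis categories
#'
#' Deterministically maps each chief complaint to one of eight categories by
#' case-insensitive keyword search. Every non-empty string maps to exactly
#' one level; unmatched text maps to `other`.
#'
#' @param chief_complaint Character vector of free-text reasons for admission.
#' @param lexicon Keyword table, as from [default_reason_lexicon()].
#' @return Factor with levels pain, neurologic, dyspnea, chemo_side_effect,
#'   abnormal_findings, dehydration, fever, other.
#' @export
#' @examples
#' group_admission_reason(c("back pain", "shortness of breath", "gratitude visit"))
group_admission_reason <- function(chief_complaint,
                                   lexicon = default_reason_lexicon()) {
  if (length(chief_complaint) == 0 || anyNA(chief_complaint) ||
      any(!nzchar(trimws(chief_complaint)))) {
    abort("chief_complaint must be non-empty text",
          class = "dasi_validation_error")
  }
  txt <- tolower(chief_complaint)
  out <- rep("other", length(txt))
  # applied in reverse so the first matching category in lexicon order wins
  for (i in rev(seq_along(lexicon))) {
    pat <- paste0(tolower(lexicon[[i]]), collapse = "|")
    hit <- stringr::str_detect(txt, stringr::regex(pat, ignore_case = TRUE))
    out[hit] <- names(lexicon)[i]
  }
  factor(out, levels = REASON_LEVELS)
}

#' Collapse rare categorical levels into "other"
#'
#' Relabels every level occurring fewer than `min_count` times as `"other"`,
#' leaving the element order untouched. Idempotent provided the pooled
#' `"other"` level itself reaches `min_count` (re-application never increases
#' the number of distinct levels).
#'
#' @param labels Character (or factor) vector of categorical values.
#' @param min_count Minimum frequency for a level to survive; default 10.
#' @return Character vector of the same length.
#' @export
#' @examples
#' collapse_rare_levels(c(rep("bladder", 10), rep("neuroendocrine", 9)))
collapse_rare_levels <- function(labels, min_count = 10) {
  if (length(labels) == 0) {
    abort("labels must be non-empty", class = "dasi_validation_error")
  }
  if (min_count < 1) {
    abort("min_count must be >= 1", class = "dasi_validation_error")
  }
  labels <- as.character(labels)
  freq <- table(labels)
  rare <- names(freq)[freq < min_count]
  out <- labels
  out[out %in% rare] <- "other"
  out
}

#' Convert Karnofsky scores to ECOG performance status
#'
#' Standard banded conversion: 90-100 -> 0, 70-80 -> 1, 50-60 -> 2,
#' 30-40 -> 3, 10-20 -> 4. A Karnofsky score of 0 has no ECOG band and is an
#' error (flag such records for review).
#'
#' @param karnofsky Integer vector of Karnofsky scores (multiples of 10,
#'   0-100); `NA` passes through as `NA`.
#' @return Integer vector of ECOG performance status values 0-4.
#' @export
#' @examples
#' karnofsky_to_ecog(c(100, 80, 40))
karnofsky_to_ecog <- function(karnofsky) {
  ok <- karnofsky %in% seq(0, 100, 10) | is.na(karnofsky)
  if (any(!ok)) {
    abort("karnofsky must be a multiple of 10 in 0-100",
          class = "dasi_validation_error")
  }
  if (any(karnofsky == 0, na.rm = TRUE)) {
    abort("karnofsky = 0 has no ECOG band; review the record",
          class = "dasi_validation_error")
  }
  band <- c(`100` = 0L, `90` = 0L, `80` = 1L, `70` = 1L, `60` = 2L,
            `50` = 2L, `40` = 3L, `30` = 3L, `20` = 4L, `10` = 4L)
  unname(band[as.character(karnofsky)])
}
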