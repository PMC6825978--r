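# The 23-factor deficit-accumulation survival index: per-factor binary
# deficits, the score in [0, 1], and the three-level risk category.

#' Default deficit factor registry
#'
#' The 23 factors and their adverse cutoffs. Each row defines one deficit:
#' the source column (a cohort field or a derived index from
#' [add_indices()]), the rule type, and its threshold(s). Rule types:
#' * `gt` / `lt` / `ge` — deficit when value >, <, or >= `threshold`;
#' * `outside` — deficit when value < `threshold` or > `threshold2`
#'   (platelet count outside 150-450);
#' * `in_set` — deficit when value is one of `levels` (comma-separated);
#' * `is_true` — deficit when a boolean flag is `TRUE`.
#'
#' Values exactly at a strict boundary (e.g. NLR = 5, sodium = 135,
#' visits = 2) are not deficits; corrected calcium's bound is inclusive
#' (>= 11). Fall-risk levels other than `high` (including `universal`) are
#' non-deficit. The registry is configuration: edit a copy, or load one from
#' YAML with [read_factor_registry()], to run cutoff sensitivity analyses.
#'
#' @return Tibble with columns `factor`, `source`, `rule`, `threshold`,
#'   `threshold2`, `levels`, `units`.
#' @export
default_factor_registry <- function() {
  tibble::tribble(
    ~factor,             ~source,                     ~rule,     ~threshold, ~threshold2, ~levels,                    ~units,
    "readmission",       "readmitted_30d",            "is_true", NA,         NA,          NA,                         "yes/no",
    "marital_support",   "marital_status",            "in_set",  NA,         NA,          "single,divorced,widowed",  "category",
    "language",          "language",                  "in_set",  NA,         NA,          "not_english",              "category",
    "fall_risk",         "fall_risk",                 "in_set",  NA,         NA,          "high",                     "category",
    "healthcare_visits", "healthcare_visits_6mo",     "gt",      2,          NA,          NA,                         "visits",
    "bmi",               "bmi",                       "lt",      19,         NA,          NA,                         "kg/m^2",
    "corrected_calcium", "corrected_calcium",         "ge",      11,         NA,          NA,                         "mg/dL",
    "creatinine",        "creatinine",                "gt",      1.3,        NA,          NA,                         "mg/dL",
    "ecog",              "ecog_ps",                   "in_set",  NA,         NA,          "2,3,4",                    "grade",
    "nlr",               "nlr",                       "gt",      5,          NA,          NA,                         "index",
    "neutrophils",       "neutrophils",               "lt",      1.8,        NA,          NA,                         "k/uL",
    "plr",               "plr",                       "gt",      250,        NA,          NA,                         "index",
    "platelets",         "platelets",                 "outside", 150,        450,         NA,                         "k/uL",
    "hemoglobin",        "hemoglobin",                "lt",      12,         NA,          NA,                         "g/dL",
    "length_of_stay",    "length_of_index_admission", "gt",      5,          NA,          NA,                         "days",
    "lymphocytes",       "lymphocytes",               "lt",      1.1,        NA,          NA,                         "k/uL",
    "sii",               "sii",                       "gt",      1600,       NA,          NA,                         "index",
    "albumin",           "albumin",                   "lt",      3.5,        NA,          NA,                         "g/dL",
    "sodium",            "sodium",                    "lt",      135,        NA,          NA,                         "mmol/L",
    "wbc",               "wbc",                       "gt",      11,         NA,          NA,                         "k/uL",
    "medications",       "n_medications",             "gt",      5,          NA,          NA,                         "count",
    "pni",               "pni",                       "lt",      45,         NA,          NA,                         "index",
    "metastasis",        "metastasis",                "is_true", NA,         NA,          NA,                         "yes/no"
  )
}

#' Read a deficit factor registry from YAML
#'
#' @param path YAML file: a list of entries with fields `factor`, `source`,
#'   `rule`, and (as required by the rule) `threshold`, `threshold2`,
#'   `levels`, `units`.
#' @return Registry tibble in the format of [default_factor_registry()].
#' @export
read_factor_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw, function(e) {
    tibble::tibble(
      factor = e$factor, source = e$source, rule = e$rule,
      threshold = as.numeric(e$threshold %||% NA),
      threshold2 = as.numeric(e$threshold2 %||% NA),
      levels = if (is.null(e$levels)) NA_character_ else
        paste(e$levels, collapse = ","),
      units = e$units %||% NA_character_
    )
  })
}

check_registry <- function(registry) {
  need <- c("factor", "source", "rule", "threshold", "threshold2", "levels")
  if (!all(need %in% names(registry))) {
    abort("malformed factor registry", class = "dasi_schema_error")
  }
  if (anyDuplicated(registry$factor) > 0) {
    abort("factor names must be unique", class = "dasi_schema_error")
  }
  bad <- setdiff(registry$rule, c("gt", "lt", "ge", "outside", "in_set", "is_true"))
  if (length(bad) > 0) {
    abort(paste0("unknown deficit rule(s): ", paste(bad, collapse = ", ")),
          class = "dasi_schema_error")
  }
  incomplete <- (registry$rule %in% c("gt", "lt", "ge", "outside") &
                   is.na(registry$threshold)) |
    (registry$rule == "outside" & is.na(registry$threshold2)) |
    (registry$rule == "in_set" &
       (is.na(registry$levels) | !nzchar(registry$levels)))
  if (any(incomplete)) {
    abort(paste0("registry rule lacks its threshold/levels for factor(s): ",
                 paste(registry$factor[incomplete], collapse = ", ")),
          class = "dasi_schema_error")
  }
  registry
}

eval_deficit <- function(x, rule, threshold, threshold2, levels) {
  out <- switch(rule,
    gt      = x > threshold,
    lt      = x < threshold,
    ge      = x >= threshold,
    outside = x < threshold | x > threshold2,
    in_set  = {
      v <- as.character(x) %in% strsplit(levels, ",")[[1]]
      v[is.na(x)] <- NA
      v
    },
    is_true = as.logical(x)
  )
  as.integer(out)
}

#' Score the 23 binary deficits for each patient
#'
#' Evaluates every registry rule against the cohort (after [add_indices()])
#' and returns the per-patient deficit vector: 1 when the adverse cutoff is
#' met, 0 otherwise, `NA` when any input to the factor is missing.
#'
#' @param data Cohort tibble carrying all registry source columns (run
#'   [add_indices()] first for the derived-index factors).
#' @param registry Factor registry, default [default_factor_registry()].
#' @return Tibble: `patient_id` (when present) plus one 0/1/`NA` integer
#'   column per factor, in registry order.
#' @export
score_deficits <- function(data, registry = default_factor_registry()) {
  registry <- check_registry(registry)
  missing_cols <- setdiff(registry$source, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("score_deficits: cohort lacks column(s) ",
                 paste(missing_cols, collapse = ", "),
                 " (did you run add_indices()?)"),
          class = "dasi_schema_error")
  }
  def <- purrr::pmap(
    registry[c("factor", "source", "rule", "threshold", "threshold2", "levels")],
    function(factor, source, rule, threshold, threshold2, levels) {
      eval_deficit(data[[source]], rule, threshold, threshold2, levels)
    }
  )
  names(def) <- registry$factor
  out <- tibble::as_tibble(def)
  if ("patient_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(patient_id = data$patient_id), out)
  }
  out
}

#' Deficit-accumulation score from a deficit vector
#'
#' Sums the non-missing deficits and divides by the denominator:
#' `"fixed23"` divides by the full factor count (the index's literal
#' construction — missing factors cannot add risk), `"evaluable"` divides by
#' the number of evaluable factors (the Rockwood frailty-index convention).
#' The score is missing when fewer than `min_evaluable` factors are
#' evaluable (default 18 of 23, ~78% completeness).
#'
#' @param deficits Deficit tibble from [score_deficits()] (a `patient_id`
#'   column, if present, is ignored). Must cover exactly the registry's
#'   factors.
#' @param denominator `"fixed23"` (default) or `"evaluable"`.
#' @param min_evaluable Completeness floor; below it the score is `NA`.
#' @param registry Factor registry the deficits were scored under.
#' @return Tibble with `n_deficits`, `n_evaluable`, `score`, `category`.
#' @export
dasi_score <- function(deficits, denominator = c("fixed23", "evaluable"),
                       min_evaluable = 18,
                       registry = default_factor_registry()) {
  denominator <- match.arg(denominator)
  registry <- check_registry(registry)
  mat <- deficits[setdiff(names(deficits), "patient_id")]
  extra <- setdiff(names(mat), registry$factor)
  missing_f <- setdiff(registry$factor, names(mat))
  if (length(extra) > 0 || length(missing_f) > 0) {
    abort(paste0("deficit map must cover exactly the registered factors",
                 if (length(extra) > 0) paste0("; unknown: ", paste(extra, collapse = ", ")),
                 if (length(missing_f) > 0) paste0("; absent: ", paste(missing_f, collapse = ", "))),
          class = "dasi_schema_error")
  }
  m <- as.matrix(mat[registry$factor])
  n_def <- rowSums(m, na.rm = TRUE)
  n_eval <- rowSums(!is.na(m))
  denom <- if (denominator == "fixed23") nrow(registry) else n_eval
  score <- ifelse(n_eval >= min_evaluable, n_def / denom, NA_real_)
  tibble::tibble(
    n_deficits = as.integer(n_def),
    n_evaluable = as.integer(n_eval),
    score = score,
    category = categorize_dasi(score, allow_na = TRUE)
  )
}

#' Categorize a deficit score into low / moderate / high risk
#'
#' Contiguous partition of \[0, 1\]: low for score <= 0.30, moderate for
#' 0.30 < score <= 0.48, high for score > 0.48, so every valid score maps to
#' exactly one category.
#'
#' @param score Numeric vector of scores in \[0, 1\].
#' @param allow_na Pass `NA` scores through as `NA` categories (used for
#'   patients below the completeness floor); default `FALSE`.
#' @return Factor with levels low, moderate, high.
#' @export
#' @examples
#' categorize_dasi(c(0.10, 0.40, 0.49))
categorize_dasi <- function(score, allow_na = FALSE) {
  if (!allow_na && anyNA(score)) {
    abort("score may not be missing", class = "dasi_validation_error")
  }
  bad <- which(!is.na(score) & (score < 0 | score > 1))
  if (length(bad) > 0) {
    abort(paste0("score outside [0, 1] at position(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "dasi_validation_error")
  }
  cut(score, breaks = c(-Inf, 0.30, 0.48, Inf),
      labels = c("low", "moderate", "high"), right = TRUE)
}

#' Score a cohort: deficits, index, and risk category in one step
#'
#' Convenience pipeline wrapper: computes derived indices if absent, scores
#' the 23 deficits, and appends `n_deficits`, `n_evaluable`, `dasi_score`
#' and `dasi_category` to the cohort.
#'
#' @inheritParams score_deficits
#' @inheritParams dasi_score
#' @param keep_deficits Also append the 23 per-factor 0/1 columns (prefixed
#'   `deficit_`); default `FALSE`.
#' @return The cohort tibble with scoring columns appended.
#' @export
add_dasi <- function(data, registry = default_factor_registry(),
                     denominator = c("fixed23", "evaluable"),
                     min_evaluable = 18, keep_deficits = FALSE) {
  denominator <- match.arg(denominator)
  if (!all(registry$source %in% names(data))) data <- add_indices(data)
  def <- score_deficits(data, registry)
  sc <- dasi_score(def, denominator, min_evaluable, registry)
  out <- dplyr::bind_cols(
    tibble::as_tibble(data),
    tibble::tibble(n_deficits = sc$n_deficits, n_evaluable = sc$n_evaluable,
                   dasi_score = sc$score, dasi_category = sc$category)
  )
  if (keep_deficits) {
    d <- def[setdiff(names(def), "patient_id")]
    names(d) <- paste0("deficit_", names(d))
    out <- dplyr::bind_cols(out, d)
  }
  out
}
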