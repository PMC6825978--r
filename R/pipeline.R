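# End-to-end analysis pipeline and report generation: read or simulate a
# cohort, derive indices and the deficit score, run the univariate screen,
# the multivariable model, Kaplan-Meier comparisons by readmission and by
# risk category, the optional imputation sensitivity analysis, and write the
# result tables as delimited text plus a markdown summary.

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort input (a file path via [read_cohort()] or a
#' `cohort_config` via [generate_cohort()]); derived indices and deficit
#' scoring; the cases-versus-controls comparison table; the univariate Cox
#' screen; the multivariable model built under the collinearity and
#' forced-covariate rules; Kaplan-Meier fits with log-rank tests by 30-day
#' readmission and by risk category; the minimum detectable hazard ratio at
#' the observed event count; and (optionally) the multiple-imputation
#' sensitivity analysis of the readmission hazard ratio.
#'
#' All randomness (simulation and imputation) flows from `seed`, so a rerun
#' with identical inputs reproduces identical tables.
#'
#' @param input A cohort file path or a `cohort_config`.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given the report tables are
#'   written there via [write_report()].
#' @param factor_registry,covariate_registry Registries (defaults as
#'   documented in [default_factor_registry()] and
#'   [default_covariate_registry()]).
#' @param denominator Deficit-score denominator policy, `"fixed23"` or
#'   `"evaluable"`.
#' @param ties Cox tie handling.
#' @param impute Run the imputation sensitivity analysis; default `TRUE`.
#' @param impute_m Number of imputed datasets; default 20.
#' @param alpha Univariate screening level.
#' @return A `dasi_report`: list with elements `cohort_summary`,
#'   `group_comparison`, `univariate`, `multivariable`, `km_readmission`,
#'   `km_dasi`, `logrank_readmission`, `logrank_dasi`, `dasi_distribution`,
#'   `power`, `sensitivity` (or `NULL`), `provenance`, and the scored
#'   analysis tibble `data`.
#' @export
run_pipeline <- function(input, seed = 1L, out_dir = NULL,
                         factor_registry = default_factor_registry(),
                         covariate_registry = default_covariate_registry(),
                         denominator = c("fixed23", "evaluable"),
                         ties = c("efron", "breslow"),
                         impute = TRUE, impute_m = 20, alpha = 0.05) {
  denominator <- match.arg(denominator)
  ties <- match.arg(ties)

  cohort <- if (inherits(input, "cohort_config")) {
    generate_cohort(input, seed = seed)
  } else if (is.character(input) && length(input) == 1) {
    read_cohort(input)
  } else if (is.data.frame(input)) {
    validate_cohort(input)
  } else {
    abort("input must be a cohort file path, data frame, or cohort_config",
          class = "dasi_validation_error")
  }

  ad <- prepare_analysis_data(cohort, factor_registry,
                              denominator = denominator)

  summarize_var <- function(x, name) {
    if (is.numeric(x)) {
      tibble::tibble(variable = name, level = NA_character_,
                     n = sum(!is.na(x)), missing = sum(is.na(x)),
                     mean = mean(x, na.rm = TRUE),
                     median = median(x, na.rm = TRUE),
                     sd = sd(x, na.rm = TRUE), percent = NA_real_)
    } else {
      tab <- table(as.character(x), useNA = "no")
      tibble::tibble(variable = name, level = names(tab),
                     n = as.integer(tab), missing = sum(is.na(x)),
                     mean = NA_real_, median = NA_real_, sd = NA_real_,
                     percent = 100 * as.integer(tab) / sum(tab))
    }
  }
  summary_vars <- setdiff(names(ad), c("patient_id", "chief_complaint",
                                       "cancer_type_raw"))
  cohort_summary <- purrr::map_dfr(summary_vars,
                                   function(v) summarize_var(ad[[v]], v))

  group_comparison <- compare_groups(
    ad, group = "readmitted_30d",
    variables = setdiff(names(ad), c("readmitted_30d", "patient_id",
                                     "chief_complaint", "cancer_type_raw",
                                     "survival_time", "event"))
  )

  screen <- univariate_screen(ad, covariate_registry, alpha = alpha,
                              ties = ties)
  multivariable <- build_multivariable(ad, screen, covariate_registry,
                                       ties = ties, budget_policy = "trim")

  km_readmission <- km_fit(ad, group = "readmitted_30d")
  logrank_readmission <- logrank_test(ad, group = "readmitted_30d")
  has_cat <- !is.na(ad$dasi_category)
  km_dasi <- km_fit(ad[has_cat, ], group = "dasi_category")
  logrank_dasi <- logrank_test(ad[has_cat, ], group = "dasi_category")

  dasi_distribution <- ad |>
    dplyr::filter(!is.na(.data$dasi_category)) |>
    dplyr::count(.data$dasi_category, name = "n") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n))

  n_events <- sum(ad$event)
  power <- tibble::tibble(
    n_events = n_events,
    allocation = mean(ad$readmitted_30d),
    min_detectable_hr = min_detectable_hr(max(n_events, 1),
                                          allocation = mean(ad$readmitted_30d))
  )

  sensitivity <- NULL
  if (impute) {
    sensitivity <- sensitivity_analysis(ad, screen, covariate_registry,
                                        focal = "readmitted_30d",
                                        m = impute_m, seed = seed,
                                        ties = ties,
                                        budget_policy = "trim")
  }

  report <- structure(list(
    cohort_summary = cohort_summary,
    group_comparison = group_comparison,
    univariate = screen,
    multivariable = multivariable,
    km_readmission = km_readmission,
    km_dasi = km_dasi,
    logrank_readmission = logrank_readmission,
    logrank_dasi = logrank_dasi,
    dasi_distribution = dasi_distribution,
    power = power,
    sensitivity = sensitivity,
    provenance = tibble::tibble(
      seed = seed,
      n = nrow(ad),
      input = if (is.character(input)) input else "simulated",
      denominator = denominator, ties = ties,
      package_version = as.character(utils::packageVersion("dasi"))
    ),
    data = ad
  ), class = "dasi_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

fmt_or_undetermined <- function(x) {
  ifelse(is.na(x), "undetermined", format(x, trim = TRUE))
}

km_summary_table <- function(km, lr) {
  g <- glance(km)
  tibble::tibble(
    stratum = as.character(g$strata), n = g$n, events = g$events,
    median_days = fmt_or_undetermined(g$median),
    conf_low = fmt_or_undetermined(g$conf_low),
    conf_high = fmt_or_undetermined(g$conf_high),
    logrank_statistic = lr$statistic, logrank_df = lr$df,
    logrank_p = lr$p_value
  )
}

#' Write a pipeline report to disk
#'
#' Writes each result table as CSV (every hazard-ratio cell carries its 95%
#' CI; undetermined median bounds are printed as "undetermined"), plus a
#' single `summary.md` overview. Output is byte-identical across reruns
#' with the same inputs and seed.
#'
#' @param report A `dasi_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(dir, paste0(name, ".csv")), na = "NA")
  }
  wr(report$cohort_summary, "cohort_summary")
  wr(report$group_comparison, "group_comparison")
  wr(tibble::as_tibble(report$univariate), "univariate_screen")
  wr(tidy(report$multivariable), "multivariable_model")
  wr(km_summary_table(report$km_readmission, report$logrank_readmission),
     "km_readmission")
  wr(km_summary_table(report$km_dasi, report$logrank_dasi), "km_dasi")
  wr(report$dasi_distribution, "dasi_distribution")
  wr(report$power, "power")
  if (!is.null(report$sensitivity)) {
    wr(tidy(report$sensitivity), "sensitivity_per_dataset")
    wr(glance(report$sensitivity), "sensitivity_summary")
  }
  wr(report$provenance, "provenance")

  md <- c(
    "# Deficit-accumulation survival analysis report", "",
    paste0("Seed ", report$provenance$seed, ", n = ", report$provenance$n,
           ", input = ", report$provenance$input, ", score denominator = ",
           report$provenance$denominator, ", ties = ",
           report$provenance$ties, "."),
    "",
    "## Survival by 30-day readmission", "",
    knit_md(km_summary_table(report$km_readmission,
                             report$logrank_readmission)),
    "",
    "## Survival by deficit-score category", "",
    knit_md(km_summary_table(report$km_dasi, report$logrank_dasi)),
    "",
    "## Multivariable Cox model", "",
    knit_md(dplyr::mutate(tidy(report$multivariable),
                          dplyr::across(dplyr::where(is.numeric),
                                        ~ round(.x, 4)))),
    ""
  )
  if (!is.null(report$sensitivity)) {
    s <- report$sensitivity
    md <- c(md, "## Imputation sensitivity", "",
            sprintf("HR range: %.1f-%.1f (m = %d); pooled HR %.2f (95%% CI %.2f-%.2f).",
                    s$hr_range["min"], s$hr_range["max"], s$m,
                    s$pooled$hazard_ratio, s$pooled$conf_low,
                    s$pooled$conf_high),
            "")
  }
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}

# minimal fixed-format markdown table (no kable dependency)
knit_md <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.character))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' @export
print.dasi_report <- function(x, ...) {
  cat("Deficit-accumulation survival analysis (n =", x$provenance$n, ")\n\n")
  cat("Survival by 30-day readmission:\n")
  print(km_summary_table(x$km_readmission, x$logrank_readmission))
  cat("\nSurvival by deficit-score category:\n")
  print(km_summary_table(x$km_dasi, x$logrank_dasi))
  cat("\nMultivariable model:\n")
  print(tidy(x$multivariable))
  if (!is.null(x$sensitivity)) {
    cat("\n")
    print(x$sensitivity)
  }
  invisible(x)
}

#' Plot the deficit-score distribution
#'
#' @param data Scored analysis tibble (with `dasi_score`, `dasi_category`).
#' @param binwidth Histogram bin width; default 1/23.
#' @return A ggplot.
#' @export
plot_dasi_distribution <- function(data, binwidth = 1 / 23) {
  ggplot2::ggplot(
    dplyr::filter(data, !is.na(.data$dasi_score)),
    ggplot2::aes(.data$dasi_score, fill = .data$dasi_category)
  ) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "Deficit-accumulation score", y = "Patients",
                  fill = "Risk category")
}
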