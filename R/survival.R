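# Estimation and testing machinery: Kaplan-Meier curves with median CIs,
# log-rank tests, Cox proportional-hazards fits, the univariate screen and
# multivariable model-building rules, group comparison tables, and the
# minimum-detectable hazard-ratio power computation. Fitting is delegated to
# the survival package; this layer owns validation, the model-building
# policy, and tidy result containers.

check_surv_inputs <- function(data, time, event) {
  for (col in c(time, event)) {
    if (!col %in% names(data)) {
      abort(paste0("column not found: ", col), class = "dasi_schema_error")
    }
  }
  if (nrow(data) < 1) {
    abort("at least one subject is required", class = "dasi_validation_error")
  }
  t <- data[[time]]
  e <- data[[event]]
  if (anyNA(t) || anyNA(e)) {
    abort("time and event may not be missing", class = "dasi_validation_error")
  }
  if (any(t <= 0)) {
    abort("survival times must be strictly positive",
          class = "dasi_validation_error")
  }
  list(time = as.numeric(t), event = as.numeric(as.logical(e)))
}

#' Kaplan-Meier survival curve with median confidence interval
#'
#' Product-limit estimate with Greenwood variance and a median (smallest
#' event time at which the curve reaches 0.5 or below) whose 95% CI comes
#' from inverting the log(-log) pointwise band (Brookmeyer-Crowley style).
#' A CI bound the band never crosses is *undetermined* and is reported as
#' `NA` (printed as "undetermined").
#'
#' @param data Data frame of subjects.
#' @param time,event Column names of the follow-up time (days, > 0) and the
#'   death indicator (`TRUE`/1 = death observed, `FALSE`/0 = censored).
#' @param group Optional column name of a stratifying factor; one curve per
#'   level.
#' @return A `dasi_km` object; see [tidy.dasi_km()] for curve coordinates
#'   and [glance.dasi_km()] for per-stratum medians.
#' @export
km_fit <- function(data, time = "survival_time", event = "event",
                   group = NULL) {
  te <- check_surv_inputs(data, time, event)
  df <- data.frame(.time = te$time, .event = te$event)
  if (!is.null(group)) {
    if (!group %in% names(data)) {
      abort(paste0("column not found: ", group), class = "dasi_schema_error")
    }
    df$.group <- factor(data[[group]])
    if (anyNA(df$.group)) df <- df[!is.na(df$.group), , drop = FALSE]
    fml <- survival::Surv(.time, .event) ~ .group
  } else {
    fml <- survival::Surv(.time, .event) ~ 1
  }
  fit <- survival::survfit(fml, data = df, conf.type = "log-log")
  structure(list(fit = fit, group = group, n = nrow(df)),
            class = "dasi_km")
}

#' @export
print.dasi_km <- function(x, ...) {
  cat("Kaplan-Meier fit (log-log median CI), n =", x$n, "\n")
  print(glance(x))
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x A `dasi_km` object.
#' @param ... Unused.
#' @return Tibble of curve coordinates: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, `std_error` (Greenwood, on the survival scale),
#'   `conf_low`, `conf_high`, and `strata` when grouped.
#' @method tidy dasi_km
#' @export
tidy.dasi_km <- function(x, ...) {
  f <- x$fit
  out <- tibble::tibble(
    time = f$time, n_risk = f$n.risk, n_event = f$n.event,
    n_censor = f$n.censor, estimate = f$surv,
    std_error = f$std.err * f$surv,   # survfit stores se of log S
    conf_low = f$lower, conf_high = f$upper
  )
  if (!is.null(f$strata)) {
    out$strata <- sub("^\\.group=", "",
                      rep(names(f$strata), f$strata))
  }
  out
}

#' Per-stratum survival summary
#'
#' @param x A `dasi_km` object.
#' @param ... Unused.
#' @return Tibble with one row per stratum: `n`, `events`, `median` (days;
#'   `NA` when the curve never reaches 0.5) and the 95% CI bounds (`NA` =
#'   undetermined).
#' @method glance dasi_km
#' @export
glance.dasi_km <- function(x, ...) {
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))
  strata <- if (is.null(x$fit$strata)) "all" else
    sub("^\\.group=", "", rownames(tab))
  td <- tidy(x)
  if (!"strata" %in% names(td)) td$strata <- "all"
  # median = smallest event time with survival <= 0.5 (not survfit's
  # convention of averaging when the curve sits exactly at 0.5)
  med <- vapply(strata, function(s) {
    d <- td[td$strata == s & td$n_event > 0 &
              td$estimate <= 0.5 + 1e-12, , drop = FALSE]
    if (nrow(d) == 0) NA_real_ else min(d$time)
  }, numeric(1))
  tibble::tibble(
    strata = strata,
    n = unname(tab[, "records"]), events = unname(tab[, "events"]),
    median = unname(med),
    conf_low = unname(tab[, "0.95LCL"]), conf_high = unname(tab[, "0.95UCL"])
  )
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `dasi_km` object.
#' @param conf_int Draw the pointwise 95% band; default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dasi_km
#' @export
autoplot.dasi_km <- function(object, conf_int = TRUE, ...) {
  d <- tidy(object)
  if (!"strata" %in% names(d)) d$strata <- "all"
  d0 <- d |>
    dplyr::group_by(.data$strata) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, estimate = 1, conf_low = 1, conf_high = 1), .x
    )) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d0, ggplot2::aes(.data$time, .data$estimate,
                                        colour = .data$strata)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days from index admission",
                  y = "Overall survival", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (conf_int) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf_low),
                                linetype = "dashed", alpha = 0.5) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
                         linetype = "dashed", alpha = 0.5)
  }
  p
}

#' K-group log-rank test
#'
#' Standard log-rank chi-square comparing the survival experience of two or
#' more groups, with `df = groups - 1` and the p-value from the chi-square
#' upper tail.
#'
#' @inheritParams km_fit
#' @param group Column name of the grouping variable (>= 2 non-empty
#'   groups).
#' @return Tibble with `statistic`, `df`, `p_value`, `n`, `n_groups`.
#' @export
logrank_test <- function(data, group, time = "survival_time",
                         event = "event") {
  te <- check_surv_inputs(data, time, event)
  if (!group %in% names(data)) {
    abort(paste0("column not found: ", group), class = "dasi_schema_error")
  }
  g <- factor(data[[group]])
  if (anyNA(g)) {
    keep <- !is.na(g)
    g <- droplevels(g[keep])
    te$time <- te$time[keep]; te$event <- te$event[keep]
  }
  if (nlevels(g) < 2) {
    abort("log-rank test needs >= 2 non-empty groups",
          class = "dasi_validation_error")
  }
  df <- data.frame(.time = te$time, .event = te$event, .group = g)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  k <- length(sd$n)
  tibble::tibble(
    statistic = sd$chisq, df = k - 1,
    p_value = pchisq(sd$chisq, df = k - 1, lower.tail = FALSE),
    n = sum(sd$n), n_groups = k
  )
}

#' Cox proportional-hazards fit
#'
#' Fits the Cox model by partial-likelihood maximization with the Efron tie
#' correction by default (heavy day-level ties are expected in admission
#' data); Wald standard errors come from the inverse observed information.
#' Monotone likelihood (complete separation in a covariate) and
#' rank-deficient designs raise diagnostic errors rather than returning
#' silently huge coefficients.
#'
#' @inheritParams km_fit
#' @param covariates Character vector of covariate column names (numeric or
#'   factor columns of `data`), or a one-sided formula of terms.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `dasi_cox` object; see [tidy.dasi_cox()] (hazard ratios with
#'   95% Wald CIs, `exp(coef +/- 1.96 SE)`) and [glance.dasi_cox()].
#' @export
cox_fit <- function(data, covariates, time = "survival_time",
                    event = "event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  te <- check_surv_inputs(data, time, event)
  if (inherits(covariates, "formula")) {
    rhs <- attr(stats::terms(covariates), "term.labels")
  } else {
    rhs <- covariates
  }
  plain <- rhs[grepl("^[A-Za-z.][A-Za-z0-9._]*$", rhs)]
  missing_cols <- setdiff(plain, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("covariate column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "dasi_schema_error")
  }
  df <- data.frame(.time = te$time, .event = te$event,
                   data[intersect(names(data), plain)],
                   check.names = FALSE)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (sum(df$.event) < 1) {
    abort("at least one event is required", class = "dasi_validation_error")
  }
  # a factor level absent from the complete-case subset is an empty contrast
  # column, not collinearity: drop it; a factor left with one level cannot
  # be estimated at all
  for (nm in intersect(plain, names(df))) {
    if (is.factor(df[[nm]])) {
      df[[nm]] <- droplevels(df[[nm]])
      if (nlevels(df[[nm]]) < 2) {
        abort(paste0("covariate ", nm,
                     " has a single level on complete cases"),
              class = "dasi_computation_error", offending_terms = nm)
      }
    }
  }
  fml <- stats::reformulate(rhs, response = quote(survival::Surv(.time, .event)))
  warn_sep <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties, x = FALSE, model = TRUE,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        warn_sep <<- c(warn_sep, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- coef(fit)
  se_all <- sqrt(diag(fit$var))
  unbounded <- !is.na(co) & (abs(co) > 15 | se_all > 50)
  # coxph reports separation as "Loglik converged before variable <i>";
  # recover the column index so the error can name the term
  for (w in warn_sep) {
    idx <- suppressWarnings(
      as.integer(unlist(regmatches(w, gregexpr("[0-9]+", w)))))
    idx <- idx[!is.na(idx) & idx >= 1 & idx <= length(co)]
    unbounded[idx] <- TRUE
  }
  if (length(warn_sep) > 0 || any(unbounded)) {
    abort(paste0("monotone partial likelihood (possible complete ",
                 "separation); coefficient unbounded: ",
                 paste(names(co)[unbounded], collapse = ", ")),
          class = "dasi_computation_error",
          offending_terms = names(co)[unbounded])
  }
  if (anyNA(coef(fit))) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "dasi_computation_error")
  }
  structure(list(fit = fit, ties = ties, covariates = rhs,
                 n = nrow(df), n_event = sum(df$.event),
                 n_dropped = sum(!cc)),
            class = "dasi_cox")
}

#' @export
print.dasi_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `dasi_cox` object.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate` (log
#'   hazard ratio), `std_error`, `hazard_ratio` (= `exp(estimate)`),
#'   `conf_low`/`conf_high` (= `exp(estimate -/+ 1.96 std_error)`),
#'   `statistic` (Wald z) and `p_value`.
#' @method tidy dasi_cox
#' @export
tidy.dasi_cox <- function(x, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- b / se
  tibble::tibble(
    term = names(b), estimate = unname(b), std_error = unname(se),
    hazard_ratio = exp(unname(b)),
    conf_low = exp(unname(b) - 1.96 * unname(se)),
    conf_high = exp(unname(b) + 1.96 * unname(se)),
    statistic = unname(z),
    p_value = 2 * pnorm(-abs(unname(z)))
  )
}

#' Fit-level summary of a Cox model
#'
#' @param x A `dasi_cox` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_event`, `n_dropped` (incomplete cases),
#'   `log_partial_likelihood` (at the maximum), `log_likelihood_null`,
#'   `score_statistic` (score test at beta = 0), `iterations`, `ties`,
#'   `converged`.
#' @method glance dasi_cox
#' @export
glance.dasi_cox <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    n = x$n, n_event = x$n_event, n_dropped = x$n_dropped,
    log_partial_likelihood = f$loglik[2], log_likelihood_null = f$loglik[1],
    score_statistic = unname(f$score), iterations = f$iter,
    ties = x$ties, converged = f$iter < 100
  )
}

#' Forest plot of hazard ratios
#'
#' @param object A `dasi_cox` object.
#' @param ... Unused.
#' @return A ggplot of hazard ratios with 95% CIs on a log scale.
#' @method autoplot dasi_cox
#' @export
autoplot.dasi_cox <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$hazard_ratio,
                                  stats::reorder(.data$term, .data$hazard_ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL)
}

# -- covariate registry and model building -----------------------------------

#' Default covariate registry for the survival screen
#'
#' One row per candidate predictor: its type, the transform applied before
#' model entry (`log` for the right-skewed labs and indices, `log1p` for
#' length of stay, whose minimum is 0 days), the reference level for
#' categorical contrasts, the collinearity group (the inflammation indices
#' NLR, neutrophils, PLR, platelets and SII are treated as one group
#' represented by NLR), and whether the covariate is forced into the
#' multivariable model regardless of the screen (cancer type and recent
#' health-care utilization).
#'
#' `admission_reason`, `cancer_type` and `dasi_category` are derived columns
#' produced by [prepare_analysis_data()].
#'
#' Covariates flagged `screen_only` (the deficit-score category, which has
#' readmission among its components, and the performance-status scores,
#' which are too sparsely documented) appear in the univariate table but are
#' never carried into the multivariable model.
#'
#' @return Tibble with columns `covariate`, `type`, `transform`,
#'   `reference`, `collinear_group`, `representative`, `forced`,
#'   `screen_only`.
#' @export
default_covariate_registry <- function() {
  tibble::tribble(
    ~covariate,                   ~type,         ~transform, ~reference, ~collinear_group, ~representative, ~forced, ~screen_only,
    "readmitted_30d",             "categorical", "none",     "FALSE",    NA,               FALSE,           FALSE,FALSE,
    "sex",                        "categorical", "none",     "male",     NA,               FALSE,           FALSE,FALSE,
    "marital_status",             "categorical", "none",     "married",  NA,               FALSE,           FALSE,FALSE,
    "language",                   "categorical", "none",     "english",  NA,               FALSE,           FALSE,FALSE,
    "race",                       "categorical", "none",     "white",    NA,               FALSE,           FALSE,FALSE,
    "fall_risk",                  "categorical", "none",     "high",     NA,               FALSE,           FALSE,FALSE,
    "admission_reason",           "categorical", "none",     "pain",     NA,               FALSE,           FALSE,FALSE,
    "cancer_type",                "categorical", "none",     "lung",     NA,               FALSE,           TRUE,FALSE,
    "dasi_category",              "categorical", "none",     "low",      NA,               FALSE,           FALSE,TRUE,
    "metastasis",                 "categorical", "none",     "FALSE",    NA,               FALSE,           FALSE,FALSE,
    "age",                        "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "healthcare_visits_6mo",      "numeric",     "none",     NA,         NA,               FALSE,           TRUE,FALSE,
    "weight_kg",                  "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "height_cm",                  "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "corrected_calcium",          "numeric",     "log",      NA,         NA,               FALSE,           FALSE,FALSE,
    "creatinine",                 "numeric",     "log",      NA,         NA,               FALSE,           FALSE,FALSE,
    "ecog_ps",                    "numeric",     "none",     NA,         NA,               FALSE,           FALSE,TRUE,
    "karnofsky",                  "numeric",     "none",     NA,         NA,               FALSE,           FALSE,TRUE,
    "hemoglobin",                 "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "length_of_index_admission",  "numeric",     "log1p",    NA,         NA,               FALSE,           FALSE,FALSE,
    "lymphocytes",                "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "nlr",                        "numeric",     "log",      NA,         "inflammation",   TRUE,            FALSE,FALSE,
    "neutrophils",                "numeric",     "log",      NA,         "inflammation",   FALSE,           FALSE,FALSE,
    "plr",                        "numeric",     "log",      NA,         "inflammation",   FALSE,           FALSE,FALSE,
    "platelets",                  "numeric",     "log",      NA,         "inflammation",   FALSE,           FALSE,FALSE,
    "sii",                        "numeric",     "log",      NA,         "inflammation",   FALSE,           FALSE,FALSE,
    "albumin",                    "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "pni",                        "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "sodium",                     "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE,
    "wbc",                        "numeric",     "log",      NA,         NA,               FALSE,           FALSE,FALSE,
    "n_medications",              "numeric",     "none",     NA,         NA,               FALSE,           FALSE,FALSE
  )
}

#' Read a covariate registry from YAML
#'
#' @param path YAML list of entries with the fields of
#'   [default_covariate_registry()].
#' @return Covariate registry tibble.
#' @export
read_covariate_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw, function(e) {
    tibble::tibble(
      covariate = e$covariate, type = e$type,
      transform = e$transform %||% "none",
      reference = e$reference %||% NA_character_,
      collinear_group = e$collinear_group %||% NA_character_,
      representative = isTRUE(e$representative),
      forced = isTRUE(e$forced),
      screen_only = isTRUE(e$screen_only)
    )
  })
}

#' Derive the analysis covariates from a raw cohort
#'
#' Adds the derived indices, the DASI score and category, the grouped
#' admission reason, and the cancer type with rare levels (count < 10)
#' collapsed to "other".
#'
#' @inheritParams add_dasi
#' @param min_count Minimum cancer-type frequency before collapsing.
#' @return The cohort tibble with `admission_reason`, `cancer_type`,
#'   `dasi_score`, `dasi_category` (and index columns) appended.
#' @export
prepare_analysis_data <- function(data, registry = default_factor_registry(),
                                  denominator = c("fixed23", "evaluable"),
                                  min_evaluable = 18, min_count = 10) {
  out <- add_dasi(data, registry, denominator, min_evaluable)
  out$admission_reason <- group_admission_reason(out$chief_complaint)
  out$cancer_type <- collapse_rare_levels(tolower(out$cancer_type_raw),
                                          min_count = min_count)
  out
}

prepare_covariate <- function(data, covariate, type, transform, reference) {
  x <- data[[covariate]]
  if (type == "numeric") {
    x <- as.numeric(x)
    x <- switch(transform, none = x, log = log(x), log1p = log1p(x),
                abort(paste0("unknown transform: ", transform),
                      class = "dasi_schema_error"))
  } else {
    x <- factor(as.character(x))
    if (!is.na(reference) && reference %in% levels(x)) {
      x <- stats::relevel(x, ref = reference)
    }
  }
  x
}

#' Univariate Cox screen over a covariate registry
#'
#' Fits one single-covariate Cox model per registry row (on the complete
#' cases for that covariate), applying the registry's transform and
#' reference level, and flags covariates whose Wald p-value falls below
#' `alpha` for inclusion in the multivariable model. Covariates that are
#' constant on their complete cases (or single-level factors) are flagged
#' `degenerate` and skipped rather than fitted.
#'
#' @param data Analysis tibble from [prepare_analysis_data()].
#' @param registry Covariate registry, default
#'   [default_covariate_registry()].
#' @param alpha Screening level; default 0.05.
#' @inheritParams cox_fit
#' @return Tibble with one row per model term: `covariate`, `term`, `n`,
#'   `n_event`, `estimate`, `hazard_ratio`, `conf_low`, `conf_high`,
#'   `p_value`, plus per-covariate flags `selected` (any term p < alpha) and
#'   `degenerate`.
#' @export
univariate_screen <- function(data, registry = default_covariate_registry(),
                              alpha = 0.05, time = "survival_time",
                              event = "event",
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  missing_cols <- setdiff(registry$covariate, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("covariate(s) absent from cohort: ",
                 paste(missing_cols, collapse = ", ")),
          class = "dasi_schema_error")
  }
  rows <- purrr::pmap(
    registry[c("covariate", "type", "transform", "reference")],
    function(covariate, type, transform, reference) {
      x <- prepare_covariate(data, covariate, type, transform, reference)
      keep <- !is.na(x) & !is.na(data[[time]]) & !is.na(data[[event]])
      xs <- if (is.factor(x)) droplevels(x[keep]) else x[keep]
      degenerate <- if (is.factor(xs)) nlevels(xs) < 2 else
        (length(unique(xs)) < 2)
      if (degenerate) {
        return(tibble::tibble(covariate = covariate, term = covariate,
                              n = sum(keep), n_event = NA_integer_,
                              estimate = NA_real_, hazard_ratio = NA_real_,
                              conf_low = NA_real_, conf_high = NA_real_,
                              p_value = NA_real_, selected = FALSE,
                              degenerate = TRUE))
      }
      df <- data.frame(.x = xs,
                       t = data[[time]][keep], e = data[[event]][keep])
      names(df)[1] <- covariate
      fit <- tryCatch(
        cox_fit(df, covariate, time = "t", event = "e", ties = ties),
        dasi_computation_error = function(e) NULL
      )
      if (is.null(fit)) {
        # monotone likelihood (e.g. a sparse level with no events): report
        # the covariate as non-estimable rather than aborting the screen
        return(tibble::tibble(covariate = covariate, term = covariate,
                              n = sum(keep), n_event = NA_integer_,
                              estimate = NA_real_, hazard_ratio = NA_real_,
                              conf_low = NA_real_, conf_high = NA_real_,
                              p_value = NA_real_, selected = FALSE,
                              degenerate = TRUE))
      }
      td <- tidy(fit)
      tibble::tibble(covariate = covariate, term = td$term, n = fit$n,
                     n_event = fit$n_event, estimate = td$estimate,
                     hazard_ratio = td$hazard_ratio, conf_low = td$conf_low,
                     conf_high = td$conf_high, p_value = td$p_value,
                     selected = any(td$p_value < alpha), degenerate = FALSE)
    }
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("dasi_screen", class(out))
  out
}

#' Build and fit the multivariable Cox model
#'
#' Applies the model-building rules to a univariate screen: take every
#' screen-selected covariate; within each declared collinearity group keep
#' only the designated representative (by default the inflammation indices
#' collapse to NLR); force-include the registry's forced covariates (cancer
#' type, recent health-care utilization) regardless of significance; and
#' refuse models whose covariate count exceeds `max_covariates` (default 13,
#' the overfitting budget for a cohort of ~271 patients). The model is then
#' fitted on complete cases.
#'
#' @inheritParams univariate_screen
#' @param screen Output of [univariate_screen()].
#' @param forced Character vector overriding the registry's forced set.
#' @param max_covariates Maximum number of covariates (model variables, not
#'   expanded contrasts).
#' @param budget_policy What to do when the selection exceeds
#'   `max_covariates`: `"error"` (default) raises a validation error listing
#'   the terms; `"trim"` keeps the forced covariates plus the
#'   strongest-screening covariates (smallest univariate p) within budget,
#'   with a warning naming the dropped terms. Under `"trim"` an unbounded
#'   coefficient (sparse zero-event factor level) is also repaired by
#'   merging the level into the reference (or dropping an unforced
#'   covariate), again with a warning; under `"error"` it raises the
#'   separation error.
#' @return A `dasi_cox` fit with attribute `model_covariates`.
#' @export
build_multivariable <- function(data, screen,
                                registry = default_covariate_registry(),
                                forced = NULL, max_covariates = 13,
                                time = "survival_time", event = "event",
                                ties = c("efron", "breslow"),
                                budget_policy = c("error", "trim")) {
  ties <- match.arg(ties)
  budget_policy <- match.arg(budget_policy)
  sel_tbl <- dplyr::distinct(screen, .data$covariate, .data$selected,
                             .data$degenerate)
  selected <- sel_tbl$covariate[sel_tbl$selected & !sel_tbl$degenerate]
  # screen-only covariates are reported in the univariate table but never
  # enter the multivariable model (e.g. the deficit-score category, which
  # contains readmission as a component, and the performance-status scores)
  if ("screen_only" %in% names(registry)) {
    selected <- setdiff(selected, registry$covariate[registry$screen_only])
  }
  # collinearity rule: any selected member of a group is replaced by the
  # group's representative
  for (grp in unique(stats::na.omit(registry$collinear_group))) {
    members <- registry$covariate[!is.na(registry$collinear_group) &
                                    registry$collinear_group == grp]
    rep_cov <- registry$covariate[registry$representative &
                                    !is.na(registry$collinear_group) &
                                    registry$collinear_group == grp][1]
    if (any(members %in% selected)) {
      selected <- c(setdiff(selected, members), rep_cov)
    }
  }
  if (is.null(forced)) forced <- registry$covariate[registry$forced]
  covs <- union(selected, forced)
  covs <- covs[match(covs, registry$covariate) |> order()]
  if (length(covs) == 0) {
    abort("no covariates selected and none forced",
          class = "dasi_validation_error")
  }
  if (length(covs) > max_covariates) {
    if (budget_policy == "error") {
      abort(paste0("model would use ", length(covs), " covariates (max ",
                   max_covariates, "): ", paste(covs, collapse = ", ")),
            class = "dasi_validation_error")
    }
    # trim policy: forced covariates always stay; the remaining slots go to
    # the covariates with the strongest univariate evidence (smallest
    # minimum screen p-value across their terms)
    optional <- setdiff(covs, forced)
    min_p <- vapply(optional, function(cv) {
      p <- screen$p_value[screen$covariate == cv]
      if (all(is.na(p))) Inf else min(p, na.rm = TRUE)
    }, numeric(1))
    n_keep <- max_covariates - length(intersect(covs, forced))
    if (n_keep < 0) {
      abort(paste0("forced covariates alone exceed the budget (max ",
                   max_covariates, ")"),
            class = "dasi_validation_error")
    }
    kept <- optional[order(min_p)][seq_len(n_keep)]
    dropped <- setdiff(optional, kept)
    warn(paste0("covariate budget exceeded; dropped weakest by screen ",
                "p-value: ", paste(dropped, collapse = ", ")),
         class = "dasi_budget_trim")
    covs <- covs[covs %in% c(kept, forced)]
  }
  reg <- registry[match(covs, registry$covariate), ]
  df <- data.frame(t = data[[time]], e = data[[event]])
  for (i in seq_len(nrow(reg))) {
    df[[reg$covariate[i]]] <- prepare_covariate(
      data, reg$covariate[i], reg$type[i], reg$transform[i], reg$reference[i]
    )
  }
  if (budget_policy == "error") {
    fit <- cox_fit(df, covs, time = "t", event = "e", ties = ties)
  } else {
    # trim policy also repairs separation: a factor level whose contrast is
    # unbounded (typically a sparse level with no events in the
    # complete-case subset) is merged into the covariate's reference level;
    # an unbounded non-factor covariate is dropped unless forced
    for (attempt in seq_len(length(covs) + 5L)) {
      fit <- tryCatch(cox_fit(df, covs, time = "t", event = "e", ties = ties),
                      dasi_computation_error = function(e) e)
      if (!inherits(fit, "condition")) break
      bad <- fit$offending_terms
      if (is.null(bad) || length(bad) == 0) stop(fit)
      owner <- vapply(bad, function(tm) {
        hits <- covs[startsWith(tm, covs)]
        if (length(hits) == 0) NA_character_ else
          hits[which.max(nchar(hits))]
      }, character(1))
      if (anyNA(owner)) stop(fit)
      progressed <- FALSE
      for (cv in unique(owner)) {
        if (is.factor(df[[cv]]) && !all(bad[owner == cv] == cv)) {
          ref <- levels(df[[cv]])[1]
          bad_lv <- sub(paste0("^", cv), "", bad[owner == cv])
          bad_lv <- intersect(bad_lv, levels(df[[cv]]))
          if (length(bad_lv) == 0) next
          warn(paste0("unbounded coefficient; merged level(s) ",
                      paste(bad_lv, collapse = ", "), " of ", cv,
                      " into reference '", ref, "'"),
               class = "dasi_separation_repair")
          x <- as.character(df[[cv]])
          x[x %in% bad_lv] <- ref
          kept_lv <- setdiff(levels(df[[cv]]), bad_lv)
          df[[cv]] <- factor(x, levels = kept_lv)
          progressed <- TRUE
          if (nlevels(df[[cv]]) < 2) {
            if (cv %in% forced) stop(fit)
            covs <- setdiff(covs, cv)
            warn(paste0("covariate ", cv, " degenerate after level merge; ",
                        "dropped"), class = "dasi_separation_repair")
          }
        } else {
          if (cv %in% forced) stop(fit)
          covs <- setdiff(covs, cv)
          warn(paste0("unbounded coefficient; dropped covariate ", cv),
               class = "dasi_separation_repair")
          progressed <- TRUE
        }
      }
      if (!progressed || length(covs) == 0) stop(fit)
    }
    if (inherits(fit, "condition")) stop(fit)
  }
  attr(fit, "model_covariates") <- covs
  fit
}

# -- group comparison ---------------------------------------------------------

#' Compare variables between groups (descriptive table with tests)
#'
#' Mirrors a cases-versus-controls characteristics table: numeric variables
#' get per-group n, mean and median with a one-way ANOVA F-test p-value on
#' complete cases; categorical variables get per-level counts and column
#' percentages with a Pearson chi-square p-value on the contingency table.
#' A variable that is constant (or all-missing in a group) is marked not
#' computable (`NA` p-value) rather than crashing.
#'
#' @param data Cohort/analysis tibble.
#' @param group Column name of the grouping variable (>= 2 groups).
#' @param variables Character vector of columns to compare; defaults to all
#'   columns except identifiers, free text and the outcome.
#' @return Tidy tibble: `variable`, `type`, `level` (categorical only),
#'   `group`, `n`, `percent`, `mean`, `median`, and the per-variable
#'   `p_value`.
#' @export
compare_groups <- function(data, group = "readmitted_30d",
                           variables = NULL) {
  if (!group %in% names(data)) {
    abort(paste0("column not found: ", group), class = "dasi_schema_error")
  }
  g <- factor(data[[group]])
  if (nlevels(droplevels(g[!is.na(g)])) < 2) {
    abort("compare_groups needs >= 2 groups", class = "dasi_validation_error")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data),
                         c(group, "patient_id", "chief_complaint",
                           "cancer_type_raw", "survival_time", "event"))
  }
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    xs <- x[keep]; gs <- droplevels(g[keep])
    if (length(xs) == 0 || nlevels(gs) < 2) {
      return(tibble::tibble(variable = v, type = "not_computable",
                            level = NA_character_, group = NA_character_,
                            n = 0L, percent = NA_real_, mean = NA_real_,
                            median = NA_real_, p_value = NA_real_))
    }
    if (is.numeric(xs)) {
      p <- if (length(unique(xs)) < 2) NA_real_ else
        summary(aov(xs ~ gs))[[1]][["Pr(>F)"]][1]
      dplyr::group_by(tibble::tibble(xs = xs, gs = gs), .data$gs) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$xs),
                         median = median(.data$xs), .groups = "drop") |>
        dplyr::transmute(variable = v, type = "numeric",
                         level = NA_character_, group = as.character(.data$gs),
                         n = .data$n, percent = NA_real_, mean = .data$mean,
                         median = .data$median, p_value = p)
    } else {
      xs <- factor(as.character(xs))
      tab <- table(xs, gs)
      p <- if (nlevels(xs) < 2) NA_real_ else
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      counts <- as.data.frame(tab, stringsAsFactors = FALSE)
      totals <- colSums(tab)
      tibble::tibble(
        variable = v, type = "categorical", level = counts$xs,
        group = counts$gs, n = counts$Freq,
        percent = 100 * counts$Freq / totals[counts$gs],
        mean = NA_real_, median = NA_real_, p_value = p
      )
    }
  })
}

#' Pearson chi-square on a contingency table
#'
#' Direct interface for worked examples: the statistic is the classical
#' sum over cells of (observed - expected)^2 / expected, with
#' `df = (rows - 1)(cols - 1)`.
#'
#' @param counts A matrix (or table) of observed counts.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_table(rbind(controls = c(25, 69, 38), cases = c(54, 64, 16)))
chisq_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || nrow(counts) < 2 || ncol(counts) < 2) {
    abort("counts must be a non-negative matrix with >= 2 rows and columns",
          class = "dasi_validation_error")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

# -- power --------------------------------------------------------------------

#' Minimum detectable hazard ratio (Schoenfeld events formula)
#'
#' For a two-sided Wald/score test of a binary exposure in a Cox model,
#' the smallest hazard ratio detectable with the given power is
#' `exp((z_(1-alpha/2) + z_power) / sqrt(d * p * (1 - p)))`, with `d` the
#' expected number of events and `p` the exposure allocation fraction.
#'
#' @param n_events Expected number of events (deaths), >= 1.
#' @param allocation Fraction of subjects in the exposed arm, in (0, 1).
#' @param alpha Two-sided significance level; default 0.05.
#' @param power Target power; default 0.80.
#' @return The minimum detectable hazard ratio (> 1).
#' @export
#' @examples
#' min_detectable_hr(100)  # ~1.75
min_detectable_hr <- function(n_events, allocation = 0.5, alpha = 0.05,
                              power = 0.80) {
  if (n_events < 1) {
    abort("n_events must be >= 1", class = "dasi_validation_error")
  }
  if (allocation <= 0 || allocation >= 1) {
    abort("allocation must be strictly inside (0, 1)",
          class = "dasi_validation_error")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must be in (0, 1)",
          class = "dasi_validation_error")
  }
  exp((qnorm(1 - alpha / 2) + qnorm(power)) /
        sqrt(n_events * allocation * (1 - allocation)))
}
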