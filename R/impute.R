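# Chained-equations multiple imputation (predictive mean matching for
# numeric variables, proportional draws for categoricals) and the
# missing-data sensitivity analysis of the multivariable hazard ratio.

pmm_draw <- function(y_obs, X_obs, X_mis, k = 5) {
  # type-0 predictive mean matching: OLS predictions, nearest-k donor pool
  df_obs <- data.frame(.y = y_obs, X_obs)
  fit <- lm(.y ~ ., data = df_obs)
  pred_obs <- unname(predict(fit))
  pred_mis <- unname(predict(fit, newdata = data.frame(X_mis)))
  vapply(pred_mis, function(p) {
    donors <- order(abs(pred_obs - p))[seq_len(min(k, length(pred_obs)))]
    y_obs[sample(donors, 1)]
  }, numeric(1))
}

#' Multiply impute missing covariate values
#'
#' Chained-equations imputation producing `m` completed cohorts: numeric
#' variables by predictive mean matching (imputed values are always drawn
#' from the observed support), categorical variables by draws proportional
#' to the observed level frequencies. The outcome (`survival_time` on the
#' log scale, and `event`) is included as a predictor but never imputed;
#' observed cells are never modified. Deterministic given `seed`.
#'
#' @param data Cohort/analysis tibble.
#' @param variables Character vector of columns to impute (and use as
#'   predictors of each other).
#' @param m Number of completed datasets; default 20.
#' @param seed Integer seed driving all imputation randomness.
#' @param cycles Chained-equation cycles per dataset; default 10.
#' @param time,event Outcome columns (predictors only).
#' @param k Donor-pool size for predictive mean matching.
#' @return List of `m` completed tibbles (class `dasi_imputations`), each
#'   with zero missing values among `variables`.
#' @export
impute_cohort <- function(data, variables, m = 20, seed, cycles = 10,
                          time = "survival_time", event = "event", k = 5) {
  if (m < 1) abort("m must be >= 1", class = "dasi_validation_error")
  if (missing(seed)) abort("seed is required for reproducibility",
                           class = "dasi_validation_error")
  missing_cols <- setdiff(c(variables, time, event), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
          class = "dasi_schema_error")
  }
  all_missing <- variables[vapply(variables, function(v) all(is.na(data[[v]])),
                                  logical(1))]
  if (length(all_missing) > 0) {
    abort(paste0("cannot impute 100%-missing variable(s): ",
                 paste(all_missing, collapse = ", ")),
          class = "dasi_validation_error")
  }
  data <- tibble::as_tibble(data)
  miss_mask <- lapply(variables, function(v) is.na(data[[v]]))
  names(miss_mask) <- variables
  numeric_var <- vapply(variables, function(v) is.numeric(data[[v]]), logical(1))
  need <- variables[vapply(miss_mask, any, logical(1))]

  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); code
  }

  outcome_predictors <- function(d) {
    data.frame(.log_time = log(d[[time]]), .event = as.numeric(d[[event]]))
  }

  complete_one <- function() {
    d <- data
    # initial fill: random draws from the observed values
    for (v in need) {
      obs <- d[[v]][!miss_mask[[v]]]
      d[[v]][miss_mask[[v]]] <- sample(obs, sum(miss_mask[[v]]), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (v in need) {
        mask <- miss_mask[[v]]
        if (numeric_var[[v]]) {
          preds <- setdiff(variables, v)
          # expand factors/characters numerically for the OLS predictor;
          # the outcome columns guarantee at least one predictor even when
          # v is the only variable being imputed
          X <- data.frame(c(
            lapply(d[preds], function(col) {
              if (is.numeric(col)) col else as.numeric(factor(col))
            }),
            outcome_predictors(d)
          ))
          vals <- pmm_draw(data[[v]][!mask],
                           X[!mask, , drop = FALSE],
                           X[mask, , drop = FALSE], k = k)
          # donors are observed values, so integer columns stay integer
          if (is.integer(data[[v]])) vals <- as.integer(vals)
          d[[v]][mask] <- vals
        } else {
          obs <- data[[v]][!mask]
          d[[v]][mask] <- sample(obs, sum(mask), replace = TRUE)
        }
      }
    }
    d
  }

  out <- withr_seed(seed, lapply(seq_len(m), function(i) complete_one()))
  # observed cells are untouched by construction; assert it anyway
  for (v in variables) {
    stopifnot(identical(out[[1]][[v]][!miss_mask[[v]]],
                        data[[v]][!miss_mask[[v]]]))
  }
  structure(out, class = c("dasi_imputations", "list"),
            variables = variables, m = m, seed = seed)
}

#' Missing-data sensitivity analysis of the multivariable model
#'
#' Refits the multivariable Cox model on each of `m` completed datasets and
#' summarizes the focal covariate: the range of its hazard ratio across the
#' fits (the primary, assumption-light summary) and the Rubin's-rules
#' pooled estimate (pooled coefficient = mean of the per-dataset
#' coefficients; total variance = within + (1 + 1/m) between).
#'
#' @inheritParams build_multivariable
#' @inheritParams impute_cohort
#' @param budget_policy Passed to [build_multivariable()].
#' @param focal Covariate whose hazard ratio is tracked (its first model
#'   term is used); default `"readmitted_30d"`.
#' @param impute_variables Columns to impute; defaults to the model
#'   covariates with any missingness (registry sources, not derived
#'   indices).
#' @return A `dasi_sensitivity` object: list with `per_dataset` (tibble of
#'   per-fit HR and p), `hr_range`, `pooled` (coefficient, SE, HR, CI, p)
#'   and the complete-case fit for reference.
#' @export
sensitivity_analysis <- function(data, screen,
                                 registry = default_covariate_registry(),
                                 focal = "readmitted_30d", m = 20, seed,
                                 impute_variables = NULL,
                                 max_covariates = 13,
                                 time = "survival_time", event = "event",
                                 ties = c("efron", "breslow"),
                                 budget_policy = c("error", "trim")) {
  ties <- match.arg(ties)
  budget_policy <- match.arg(budget_policy)
  if (missing(seed)) abort("seed is required for reproducibility",
                           class = "dasi_validation_error")
  cc_fit <- build_multivariable(data, screen, registry,
                                max_covariates = max_covariates,
                                time = time, event = event, ties = ties,
                                budget_policy = budget_policy)
  covs <- attr(cc_fit, "model_covariates")
  if (is.null(impute_variables)) {
    impute_variables <- covs[vapply(covs, function(v) anyNA(data[[v]]),
                                    logical(1))]
  }
  completed <- if (length(impute_variables) == 0) {
    structure(rep(list(tibble::as_tibble(data)), m),
              class = c("dasi_imputations", "list"))
  } else {
    impute_cohort(data, impute_variables, m = m, seed = seed,
                  time = time, event = event)
  }
  fits <- vector("list", m)
  for (i in seq_len(m)) {
    fits[[i]] <- tryCatch(
      build_multivariable(completed[[i]], screen, registry,
                          max_covariates = max_covariates,
                          time = time, event = event, ties = ties,
                          budget_policy = budget_policy),
      error = function(e) {
        abort(paste0("model fit failed on completed dataset ", i, ": ",
                     conditionMessage(e)),
              class = "dasi_computation_error")
      }
    )
  }
  focal_term <- function(fit) {
    td <- tidy(fit)
    hit <- td[startsWith(td$term, focal), , drop = FALSE]
    if (nrow(hit) == 0) {
      abort(paste0("focal covariate ", focal, " not in model"),
            class = "dasi_schema_error")
    }
    hit[1, ]
  }
  per <- purrr::imap_dfr(fits, function(f, i) {
    td <- focal_term(f)
    tibble::tibble(dataset = i, term = td$term, estimate = td$estimate,
                   std_error = td$std_error, hazard_ratio = td$hazard_ratio,
                   p_value = td$p_value)
  })
  qbar <- mean(per$estimate)
  W <- mean(per$std_error^2)
  B <- if (m > 1) stats::var(per$estimate) else 0
  Tvar <- W + (1 + 1 / m) * B
  pooled_se <- sqrt(Tvar)
  z <- qbar / pooled_se
  pooled <- tibble::tibble(
    estimate = qbar, std_error = pooled_se, hazard_ratio = exp(qbar),
    conf_low = exp(qbar - 1.96 * pooled_se),
    conf_high = exp(qbar + 1.96 * pooled_se),
    p_value = 2 * pnorm(-abs(z)),
    within_variance = W, between_variance = B
  )
  structure(
    list(per_dataset = per,
         hr_range = c(min = min(per$hazard_ratio), max = max(per$hazard_ratio)),
         pooled = pooled, complete_case = focal_term(cc_fit),
         focal = focal, m = m, seed = seed),
    class = "dasi_sensitivity"
  )
}

#' @export
print.dasi_sensitivity <- function(x, ...) {
  cat("Multiple-imputation sensitivity analysis (m = ", x$m, ", focal = ",
      x$focal, ")\n", sep = "")
  cat(sprintf("HR range: %.2f-%.2f\n", x$hr_range["min"], x$hr_range["max"]))
  cat(sprintf("Pooled HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$pooled$hazard_ratio, x$pooled$conf_low, x$pooled$conf_high,
              x$pooled$p_value))
  invisible(x)
}

#' Tidy a sensitivity analysis
#'
#' @param x A `dasi_sensitivity` object.
#' @param ... Unused.
#' @return The per-dataset tibble of focal hazard ratios.
#' @method tidy dasi_sensitivity
#' @export
tidy.dasi_sensitivity <- function(x, ...) x$per_dataset

#' One-row summary of a sensitivity analysis
#'
#' @param x A `dasi_sensitivity` object.
#' @param ... Unused.
#' @return One-row tibble: `m`, `hr_min`, `hr_max`, pooled estimate, CI and
#'   p-value.
#' @method glance dasi_sensitivity
#' @export
glance.dasi_sensitivity <- function(x, ...) {
  tibble::tibble(m = x$m, hr_min = unname(x$hr_range["min"]),
                 hr_max = unname(x$hr_range["max"]),
                 pooled_hr = x$pooled$hazard_ratio,
                 conf_low = x$pooled$conf_low,
                 conf_high = x$pooled$conf_high,
                 p_value = x$pooled$p_value)
}
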