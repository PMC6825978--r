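test_that("impute_cohort fills every gap, never touches observed cells, and is seed-deterministic", {
  cohort <- generate_cohort(default_study_config(n = 200, seed = 41))
  vars <- c("albumin", "sodium", "ecog_ps")
  expect_true(any(is.na(cohort$albumin)) || any(is.na(cohort$ecog_ps)))
  imps <- impute_cohort(cohort, vars, m = 3, seed = 7)
  for (d in imps) {
    for (v in vars) expect_false(anyNA(d[[v]]))
  }
  for (v in vars) {
    obs <- !is.na(cohort[[v]])
    expect_identical(imps[[1]][[v]][obs], cohort[[v]][obs])
    # imputed numerics come from the observed support (predictive mean
    # matching draws donors, never extrapolates)
    expect_true(all(imps[[1]][[v]][!obs] %in% cohort[[v]][obs]))
  }
  again <- impute_cohort(cohort, vars, m = 3, seed = 7)
  expect_identical(imps[[2]], again[[2]])
  other <- impute_cohort(cohort, vars, m = 3, seed = 8)
  expect_false(identical(imps[[1]], other[[1]]))
})

test_that("impute_cohort validates its arguments", {
  cohort <- generate_cohort(default_study_config(n = 50, seed = 43))
  expect_error(impute_cohort(cohort, "albumin", m = 0, seed = 1),
               class = "dasi_validation_error")
  expect_error(impute_cohort(cohort, "albumin", m = 5),
               class = "dasi_validation_error")  # seed required
  expect_error(impute_cohort(cohort, "not_a_column", m = 2, seed = 1),
               class = "dasi_schema_error")
  gone <- cohort
  gone$albumin <- NA_real_
  expect_error(impute_cohort(gone, "albumin", m = 2, seed = 1),
               class = "dasi_validation_error")
})

test_that("rubin pooling combines within- and between-imputation variance", {
  cfg <- default_study_config(n = 600, seed = 47)
  cohort <- generate_cohort(cfg)
  ad <- prepare_analysis_data(cohort, default_factor_registry())
  screen <- suppressWarnings(univariate_screen(ad, default_covariate_registry()))
  sens <- suppressWarnings(
    sensitivity_analysis(ad, screen, m = 4, seed = 47,
                         budget_policy = "trim"))
  per <- tidy(sens)
  expect_identical(nrow(per), 4L)
  qbar <- mean(per$estimate)
  W <- mean(per$std_error^2)
  B <- var(per$estimate)
  expect_equal(sens$pooled$estimate, qbar)
  expect_equal(sens$pooled$std_error, sqrt(W + (1 + 1 / 4) * B))
  expect_equal(unname(sens$hr_range["min"]), min(per$hazard_ratio))
  expect_equal(unname(sens$hr_range["max"]), max(per$hazard_ratio))
  g <- glance(sens)
  expect_equal(g$pooled_hr, exp(qbar))
})
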