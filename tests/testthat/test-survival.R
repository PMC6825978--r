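test_that("km_fit summarizes strata with undetermined medians as NA", {
  d <- tibble::tibble(
    survival_time = c(5, 8, 10, 12, 200, 210, 220, 230),
    event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    grp = rep(c("a", "b"), each = 4)
  )
  g <- glance(km_fit(d, group = "grp"))
  expect_identical(g$strata, c("a", "b"))
  expect_equal(g$median[g$strata == "a"], 8)  # S drops to 0.5 at 8
  expect_true(is.na(g$median[g$strata == "b"]))
  expect_true(is.na(g$conf_high[g$strata == "b"]))
})

test_that("cox_fit returns exchangeable-group and error contracts", {
  # identical time/event data in both groups: coefficient 0, HR 1
  d <- tibble::tibble(
    survival_time = rep(c(3, 6, 9, 12), 2),
    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
    g = rep(c(0, 1), each = 4)
  )
  td <- tidy(cox_fit(d, "g"))
  expect_equal(td$estimate, 0, tolerance = 1e-8)
  expect_equal(td$hazard_ratio, 1, tolerance = 1e-8)

  # complete separation in a binary covariate is a diagnostic error
  sep <- tibble::tibble(
    survival_time = c(1, 2, 3, 4, 100, 110, 120, 130),
    event = c(rep(TRUE, 4), rep(FALSE, 4)),
    x = c(rep(1, 4), rep(0, 4))
  )
  expect_error(cox_fit(sep, "x"), class = "dasi_computation_error")

  # a duplicated column is rank deficiency, named in the error
  dup <- d
  dup$g2 <- dup$g
  expect_error(cox_fit(dup, c("g", "g2")), "g2",
               class = "dasi_computation_error")

  # unknown covariate is a schema error
  expect_error(cox_fit(d, "nope"), class = "dasi_schema_error")
})

test_that("efron and breslow tie handling are both available and differ on tied data", {
  d <- tibble::tibble(
    survival_time = c(2, 2, 2, 5, 5, 8, 9, 12),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    x = c(1, 0, 1, 1, 0, 0, 1, 0)
  )
  b_efron <- tidy(cox_fit(d, "x", ties = "efron"))$estimate
  b_breslow <- tidy(cox_fit(d, "x", ties = "breslow"))$estimate
  expect_false(isTRUE(all.equal(b_efron, b_breslow)))
  expect_identical(glance(cox_fit(d, "x"))$ties, "efron")
})

test_that("wald intervals use the literal 1.96 multiplier", {
  d <- tibble::tibble(
    survival_time = c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    g = rep(c(0, 1), 5)
  )
  td <- tidy(cox_fit(d, "g"))
  expect_equal(td$conf_low, exp(td$estimate - 1.96 * td$std_error))
  expect_equal(td$conf_high, exp(td$estimate + 1.96 * td$std_error))
})

test_that("the univariate screen flags degenerate covariates instead of failing", {
  cohort <- generate_cohort(default_study_config(n = 120, seed = 21))
  ad <- prepare_analysis_data(cohort, default_factor_registry())
  ad$flat <- 1  # constant covariate
  reg <- tibble::tibble(covariate = "flat", type = "numeric",
                        transform = "none", reference = NA_character_,
                        collinear_group = NA_character_,
                        representative = FALSE, forced = FALSE,
                        screen_only = FALSE)
  sc <- univariate_screen(ad, reg)
  expect_true(all(sc$degenerate))
  expect_false(any(sc$selected))
})

test_that("model building applies the collinearity rule, forced set and budget", {
  cohort <- generate_cohort(default_study_config(n = 400, seed = 23))
  ad <- prepare_analysis_data(cohort, default_factor_registry())
  registry <- default_covariate_registry()
  screen <- suppressWarnings(univariate_screen(ad, registry))

  # force the worked selection {nlr, sii, wbc}: the inflammation group
  # collapses to its representative, so the model is {nlr, wbc} + forced
  screen$selected <- screen$covariate %in% c("nlr", "sii", "wbc")
  fit <- build_multivariable(ad, screen, registry)
  covs <- attr(fit, "model_covariates")
  expect_true(all(c("nlr", "wbc") %in% covs))
  expect_false(any(c("sii", "plr", "platelets", "neutrophils") %in% covs))
  expect_true(all(c("cancer_type", "healthcare_visits_6mo") %in% covs))

  # over-budget selection is an explicit error by default
  expect_error(build_multivariable(ad, screen, registry, max_covariates = 2),
               class = "dasi_validation_error")
  # ... and a warning-with-trim under the pipeline policy
  expect_warning(
    trimmed <- build_multivariable(ad, screen, registry, max_covariates = 3,
                                   budget_policy = "trim"),
    class = "dasi_budget_trim"
  )
  expect_lte(length(attr(trimmed, "model_covariates")), 3)
  expect_true(all(c("cancer_type", "healthcare_visits_6mo")
                  %in% attr(trimmed, "model_covariates")))

  # nothing selected and nothing forced is an error
  screen$selected <- FALSE
  expect_error(build_multivariable(ad, screen, registry, forced = character(0)),
               class = "dasi_validation_error")
})

test_that("screen-only covariates never enter the multivariable model", {
  cohort <- generate_cohort(default_study_config(n = 400, seed = 29))
  ad <- prepare_analysis_data(cohort, default_factor_registry())
  registry <- default_covariate_registry()
  screen <- suppressWarnings(univariate_screen(ad, registry))
  screen$selected <- screen$covariate %in% c("dasi_category", "ecog_ps")
  fit <- build_multivariable(ad, screen, registry)
  covs <- attr(fit, "model_covariates")
  expect_false(any(c("dasi_category", "ecog_ps", "karnofsky") %in% covs))
})

test_that("group comparison reports ANOVA and chi-square p-values", {
  cohort <- generate_cohort(default_study_config(n = 200, seed = 33))
  ad <- prepare_analysis_data(cohort, default_factor_registry())
  cmp <- compare_groups(ad, group = "readmitted_30d",
                        variables = c("age", "albumin", "marital_status"))
  expect_true(all(c("variable", "p_value") %in% names(cmp)))
  alb <- cmp[cmp$variable == "albumin", ]
  expect_true(all(is.finite(alb$p_value)))
  # the numeric p matches a direct one-way ANOVA
  p_hand <- summary(aov(ad$albumin ~ factor(ad$readmitted_30d)))[[1]][1, "Pr(>F)"]
  expect_equal(unique(alb$p_value), p_hand, tolerance = 1e-10)
})

test_that("minimum detectable hazard ratio follows the events formula", {
  expect_equal(min_detectable_hr(100),
               exp((qnorm(0.975) + qnorm(0.80)) / sqrt(100 * 0.25)))
  expect_equal(min_detectable_hr(100), 1.7513, tolerance = 1e-4)
  # more events -> smaller detectable effect
  expect_lt(min_detectable_hr(200), min_detectable_hr(100))
  expect_error(min_detectable_hr(0), class = "dasi_validation_error")
  expect_error(min_detectable_hr(100, allocation = 1),
               class = "dasi_validation_error")
})
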