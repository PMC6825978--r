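test_that("generation is deterministic in the seed and validates its own output", {
  cfg <- default_study_config(n = 80, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(default_study_config(n = 80, seed = 14))
  expect_false(identical(a$survival_time, c2$survival_time))
  expect_silent(validate_cohort(a))
  expect_identical(nrow(a), 80L)
})

test_that("marginals, event fraction and missingness match the configured targets", {
  cohort <- generate_cohort(default_study_config(n = 5000, seed = 19))
  expect_lt(abs(mean(cohort$sodium, na.rm = TRUE) - 136), 0.5)
  expect_lt(abs(mean(cohort$albumin, na.rm = TRUE) - 3.42), 0.1)
  expect_lt(abs(mean(cohort$event) - 0.41), 0.05)
  expect_lt(abs(mean(cohort$readmitted_30d) - 0.5), 0.05)
  miss <- default_missingness()
  expect_lt(abs(mean(is.na(cohort$ecog_ps)) - miss[["ecog_ps"]]), 0.03)
  expect_true(all(cohort$survival_time >= 1))
  expect_true(all(cohort$survival_time == floor(cohort$survival_time)))
})

test_that("the generating truth drives survival and matches the measured score", {
  cohort <- generate_cohort(default_study_config(n = 3000, seed = 23))
  truth <- attr(cohort, "truth")
  expect_identical(nrow(truth), nrow(cohort))
  # the measured score is a close proxy of the generating score (ratio-index
  # factors are emergent from the drawn labs, so agreement is high, not 1)
  scored <- add_dasi(cohort)
  ok <- !is.na(scored$dasi_score)
  expect_gt(cor(scored$dasi_score[ok], truth$true_score[ok]), 0.8)
  # higher true score means shorter observed survival on average
  hi <- truth$true_score > median(truth$true_score)
  expect_gt(mean(cohort$event[hi]), mean(cohort$event[!hi]))
})

test_that("all-zero deficit probabilities give a deficit-free truth", {
  cfg <- default_study_config(n = 40, seed = 29)
  cfg$deficit_probs[] <- 0
  cfg$missingness <- numeric(0)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  expect_true(all(truth$true_score == 0))
  expect_false(any(cohort$readmitted_30d))
})

test_that("config validation rejects impossible settings", {
  cfg <- default_study_config(n = 10, seed = 1)
  bad_n <- cfg
  bad_n$n <- 0
  expect_error(generate_cohort(bad_n), class = "dasi_validation_error")
  bad_p <- cfg
  bad_p$p_readmit <- 1.5
  expect_error(generate_cohort(bad_p), class = "dasi_validation_error")
  bad_rho <- cfg
  bad_rho$rho <- -0.2
  expect_error(generate_cohort(bad_rho), class = "dasi_validation_error")
})
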