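test_that("denominator conventions and the completeness floor behave as documented", {
  p <- base_patient()
  p$sodium <- NA          # one unevaluable factor, zero deficits elsewhere
  p$albumin <- 3.0        # one deficit
  def <- score_deficits(p)
  fixed <- dasi_score(def, denominator = "fixed23")
  expect_identical(fixed$n_evaluable, 22L)
  expect_equal(fixed$score, 1 / 23)
  evaluable <- dasi_score(def, denominator = "evaluable")
  expect_equal(evaluable$score, 1 / 22)

  # below the floor the score (and category) are missing
  p2 <- base_patient()
  p2[c("sodium", "albumin", "wbc", "nlr", "plr", "sii")] <- NA_real_
  def2 <- score_deficits(p2)
  expect_identical(dasi_score(def2)$n_evaluable, 17L)
  expect_true(is.na(dasi_score(def2)$score))
  expect_true(is.na(dasi_score(def2)$category))
})

test_that("categorize_dasi validates its input", {
  expect_error(categorize_dasi(c(0.2, NA)), class = "dasi_validation_error")
  expect_error(categorize_dasi(1.2), class = "dasi_validation_error")
  expect_equal(as.character(categorize_dasi(NA_real_, allow_na = TRUE)),
               NA_character_)
})

test_that("add_dasi appends score columns and optionally the deficit map", {
  cohort <- generate_cohort(default_study_config(n = 50, seed = 9))
  scored <- add_dasi(cohort)
  expect_true(all(c("n_deficits", "n_evaluable", "dasi_score",
                    "dasi_category") %in% names(scored)))
  expect_identical(nrow(scored), nrow(cohort))
  with_def <- add_dasi(cohort, keep_deficits = TRUE)
  def_cols <- grep("^deficit_", names(with_def), value = TRUE)
  expect_length(def_cols, 23)
  # the score is the deficit count over 23 wherever evaluable
  ok <- !is.na(with_def$dasi_score)
  expect_equal(with_def$dasi_score[ok], with_def$n_deficits[ok] / 23)
})

test_that("the shipped YAML factor registry equals the built-in default", {
  path <- system.file("extdata", "factor_registry.yaml", package = "dasi")
  expect_true(nzchar(path))
  from_yaml <- read_factor_registry(path)
  expect_equal(as.data.frame(from_yaml),
               as.data.frame(default_factor_registry()))
})

test_that("registry validation rejects malformed registries", {
  reg <- default_factor_registry()
  dup <- rbind(reg, reg[1, ])
  expect_error(score_deficits(base_patient(), dup), class = "dasi_schema_error")
  bad_rule <- reg
  bad_rule$rule[1] <- "unknown_rule"
  expect_error(score_deficits(base_patient(), bad_rule),
               class = "dasi_schema_error")
  no_thresh <- reg
  no_thresh$threshold[no_thresh$rule == "gt"][1] <- NA
  expect_error(score_deficits(base_patient(), no_thresh),
               class = "dasi_schema_error")
})

test_that("score_deficits names the missing source columns", {
  p <- base_patient()
  p$nlr <- NULL
  expect_error(score_deficits(p), "nlr", class = "dasi_schema_error")
})
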