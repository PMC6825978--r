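test_that("cohort file round-trip preserves values and types", {
  cohort <- generate_cohort(default_study_config(n = 60, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_identical(back$patient_id, cohort$patient_id)
  expect_identical(back$readmitted_30d, cohort$readmitted_30d)
  expect_equal(back$albumin, cohort$albumin)
  expect_identical(back$event, cohort$event)
  expect_identical(nrow(back), nrow(cohort))
})

test_that("read_cohort rejects missing files and malformed content", {
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")),
               class = "dasi_io_error")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age", "p1,not-a-number"), bad)
  expect_error(read_cohort(bad), class = "dasi_parse_error")
  # a file missing schema columns (but parseable) is a schema error
  incomplete <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,age", "p1,33"), incomplete)
  expect_error(read_cohort(incomplete), class = "dasi_schema_error")
})

test_that("validate_cohort enforces ids, outcome and value constraints", {
  cohort <- generate_cohort(default_study_config(n = 40, seed = 3))
  dup <- cohort
  dup$patient_id[2] <- dup$patient_id[1]
  expect_error(validate_cohort(dup), class = "dasi_validation_error")
  bad_time <- cohort
  bad_time$survival_time[1] <- 0
  expect_error(validate_cohort(bad_time), class = "dasi_validation_error")
  bad_ecog <- cohort
  bad_ecog$ecog_ps[1] <- 7
  expect_error(validate_cohort(bad_ecog), class = "dasi_validation_error")
  na_event <- cohort
  na_event$event[1] <- NA
  expect_error(validate_cohort(na_event), class = "dasi_validation_error")
})

test_that("admission reasons map by first-matching lexicon category", {
  got <- group_admission_reason(c(
    "Abdominal Pain", "syncope and collapse", "shortness of breath",
    "nausea and vomiting after chemotherapy", "abnormal EKG",
    "dehydration", "neutropenic fever", "generalized weakness"
  ))
  expect_equal(as.character(got),
               c("pain", "neurologic", "dyspnea", "chemo_side_effect",
                 "abnormal_findings", "dehydration", "fever", "other"))
  # first category in lexicon order wins on multi-match text
  expect_equal(as.character(group_admission_reason("chest pain with dyspnea")),
               "pain")
  expect_error(group_admission_reason(c("pain", NA)),
               class = "dasi_validation_error")
})

test_that("collapse_rare_levels folds small groups into 'other'", {
  x <- c(rep("lung", 12), rep("breast", 11), rep("rare1", 3), rep("rare2", 2))
  got <- collapse_rare_levels(x, min_count = 10)
  expect_setequal(unique(got), c("lung", "breast", "other"))
  expect_identical(sum(got == "other"), 5L)
})

test_that("karnofsky_to_ecog maps bands and rejects invalid scores", {
  expect_identical(karnofsky_to_ecog(c(100, 90, 80, 70, 50, 30, 10)),
                   c(0L, 0L, 1L, 1L, 2L, 3L, 4L))
  expect_identical(karnofsky_to_ecog(NA_real_), NA_integer_)
  expect_error(karnofsky_to_ecog(0), class = "dasi_validation_error")
  expect_error(karnofsky_to_ecog(85), class = "dasi_validation_error")
})
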