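test_that("derived indices match their hand-computed definitions", {
  d <- tibble::tibble(
    neutrophils = 6, lymphocytes = 1.5, platelets = 300, albumin = 3.8,
    weight_kg = 72, height_cm = 160
  )
  got <- add_indices(d)
  expect_equal(got$nlr, 6 / 1.5)
  expect_equal(got$plr, 300 / 1.5)
  expect_equal(got$sii, 300 * 6 / 1.5)
  expect_equal(got$pni, 3.8 * 1.5)
  expect_equal(got$bmi, 72 / 1.6^2)
})

test_that("the alternative prognostic-nutrition convention is available", {
  d <- tibble::tibble(
    neutrophils = 6, lymphocytes = 1.5, platelets = 300, albumin = 3.8,
    weight_kg = 72, height_cm = 160
  )
  got <- add_indices(d, pni_convention = "onodera")
  expect_equal(got$pni, 10 * 3.8 + 5 * 1.5)
})

test_that("indices propagate missingness and reject non-positive lymphocytes", {
  d <- tibble::tibble(
    neutrophils = c(6, NA), lymphocytes = c(1.5, 2), platelets = c(NA, 250),
    albumin = c(3.8, NA), weight_kg = c(NA, 70), height_cm = c(160, 170)
  )
  got <- add_indices(d)
  expect_true(is.na(got$plr[1]))
  expect_true(is.na(got$nlr[2]))
  expect_true(is.na(got$pni[2]))
  expect_true(is.na(got$bmi[1]))
  bad <- d
  bad$lymphocytes[1] <- 0
  expect_error(add_indices(bad), class = "dasi_computation_error")
})

test_that("calcium is albumin-corrected by the standard formula", {
  expect_equal(correct_calcium(9.0, 4.0), 9.0)
  expect_equal(correct_calcium(9.0, 3.0), 9.8)
  expect_true(is.na(correct_calcium(NA, 3.5)))
})
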