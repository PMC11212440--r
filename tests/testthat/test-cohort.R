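make_collection <- function(dur_h, vol_ml, una = 100, uk = 50, ucrea = 80) {
  tibble::tibble(
    dur_h = dur_h, vol_ml = vol_ml,
    u24_una_mmol_l = una, u24_uk_mmol_l = uk, u24_ucrea_mg_dl = ucrea
  )
}

test_that("collection screening applies the protocol rules with accepted boundaries", {
  x <- make_collection(
    dur_h = c(24, 19.9, 24, 20, 28, 28.1, 20, 24),
    vol_ml = c(500, 2000, 200, 2000, 2000, 2000, 240, 250)
  )
  out <- screen_collections(x)
  expect_equal(out$collection_ok,
               c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$reject_reason,
               c(NA, "duration_short", "volume", NA, NA, "duration_long", NA, NA))
  # volume is a daily rate: 240 ml over 20 h is 288 ml/d, acceptable;
  # the same 240 ml over 24 h would be rejected
  expect_false(screen_collections(make_collection(24, 240))$collection_ok)
})

test_that("correction to 24h rescales totals linearly and flags corrected rows", {
  exact <- normalize_collections(make_collection(24, 2000, una = 100))
  expect_equal(exact$na24_mmol_d, 200)
  expect_equal(exact$na24_mg_d, 23 * 200)
  expect_false(exact$normalized)

  short <- normalize_collections(make_collection(20.8, 2000, una = 100))
  expect_equal(short$na24_mmol_d, 200 * 24 / 20.8, tolerance = 1e-12)
  expect_true(short$normalized)

  long <- normalize_collections(make_collection(26.7, 2670, una = 100))
  expect_equal(long$na24_mmol_d, 240.0, tolerance = 1e-12)

  # doubling both volume and concentration quadruples daily excretion
  base <- normalize_collections(make_collection(22, 1500, una = 80))
  quad <- normalize_collections(make_collection(22, 3000, una = 160))
  expect_equal(quad$na24_mmol_d, 4 * base$na24_mmol_d, tolerance = 1e-12)

  # potassium and creatinine are rescaled with the same factor
  expect_equal(short$k24_mmol_d, 50 * 2 * 24 / 20.8, tolerance = 1e-12)
  expect_equal(short$crea24_g_d, 80 * 10 * 2 / 1000 * 24 / 20.8, tolerance = 1e-12)

  expect_error(normalize_collections(make_collection(19, 2000)), "screen")
})

test_that("spot averaging is the component-wise mean and propagates missingness", {
  x <- tibble::tibble(
    am_una_mmol_l = c(80, 19, 50, NA),
    pm_una_mmol_l = c(120, 0, 50, 60),
    am_uk_mmol_l = c(40, 10, 30, 20),
    pm_uk_mmol_l = c(60, 30, 30, NA),
    am_ucrea_mg_dl = c(100, 50, 80, 90),
    pm_ucrea_mg_dl = c(140, 150, 80, 110)
  )
  out <- average_spot(x)
  expect_equal(out$avg_una_mmol_l, c(100, 9.5, 50, NA))
  expect_equal(out$avg_uk_mmol_l, c(50, 20, 30, NA))
  # am = pm gives back the shared value (idempotence)
  expect_equal(out$avg_una_mmol_l[3], x$am_una_mmol_l[3])
})

test_that("creatinine adjustment expresses sodium per gram of creatinine", {
  expect_equal(creatinine_adjust(100, 100), 100)
  expect_equal(creatinine_adjust(0, 80), 0)
  expect_equal(creatinine_adjust(50, 200), 25)
  expect_error(creatinine_adjust(50, 0), "positive")
})

test_that("cohort files round-trip with their seed recorded", {
  cohort <- simulate_cohort(n = 12, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_equal(readLines(path, n = 1), "# seed: 77")
  back <- read_cohort(path)
  expect_equal(back, cohort, ignore_attr = TRUE)
  expect_error(
    suppressWarnings(read_cohort(withr::local_tempfile(lines = "id,sex\n1,male",
                                                       fileext = ".csv"))),
    "missing required column"
  )
})
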