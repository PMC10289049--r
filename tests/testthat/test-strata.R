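test_that("age band edges follow the published bands", {
  d <- data.frame(tc = 200, hdl = 50, tg = 120, age = c(17.9, 18, 59.9, 60))
  expect_equal(stratum_filter(d, "age_lt18")$n_in, 1L)
  expect_equal(stratum_filter(d, "age_18_59")$n_in, 2L)
  expect_equal(stratum_filter(d, "age_ge60")$n_in, 1L)
})

test_that("clinical thresholds use the printed inequality directions", {
  d <- data.frame(tc = 200, hdl = 50, tg = 120,
                  egfr = c(59.9, 60, 80),
                  tsh = c(4.5, 4.51, 0.5),
                  hscrp = c(2, 1.99, 5),
                  diabetes_dx = FALSE,
                  a1c = c(6.5, 6.51, 5),
                  fasting_glucose = c(126, 100, 125.9))
  expect_equal(stratum_filter(d, "kidney_disease")$n_in, 1L)     # eGFR < 60 strict
  expect_equal(stratum_filter(d, "thyroid_dysfunction")$n_in, 1L) # 4.5 and 0.5 are normal
  expect_equal(stratum_filter(d, "inflammation")$n_in, 2L)        # hsCRP >= 2 inclusive
  expect_equal(stratum_filter(d, "diabetes")$n_in, 2L)            # a1c > 6.5 or glucose >= 126
})

test_that("diabetes is the OR of diagnosis, A1c and fasting glucose", {
  d <- data.frame(tc = 200, hdl = 50, tg = 120,
                  diabetes_dx = c(TRUE, FALSE, NA, NA),
                  a1c = c(NA, NA, 7.2, NA),
                  fasting_glucose = c(NA, 100, NA, NA))
  s <- stratum_filter(d, "diabetes")
  expect_equal(s$n_in, 2L)      # dx flag; high A1c
  expect_equal(s$n_missing, 1L) # all three components unobserved
  expect_equal(s$n_out, 1L)
})

test_that("band families are mutually exclusive and exhaustive", {
  co <- simulate_cohort(cohort_config(n = 3000, seed = 71))
  has_age <- !is.na(co$age)
  in_band <- stratum_filter(co, "age_lt18")$n_in +
    stratum_filter(co, "age_18_59")$n_in +
    stratum_filter(co, "age_ge60")$n_in
  expect_equal(in_band, sum(has_age))
  tg_bands <- stratum_filter(co, "tg_lt400")$n_in +
    stratum_filter(co, "tg_400_799")$n_in
  expect_equal(tg_bands, sum(co$tg < 800))
  # 150-399 is a sub-band of <400
  expect_lte(stratum_filter(co, "tg_150_399")$n_in,
             stratum_filter(co, "tg_lt400")$n_in)
})

test_that("records are accounted for: in + out + missing = total", {
  co <- simulate_cohort(cohort_config(n = 500, seed = 72))
  co$age[1:25] <- NA
  for (s in cohort_strata()) {
    f <- stratum_filter(co, s)
    expect_equal(f$n_in + f$n_out + f$n_missing, f$n_total, label = s)
  }
})

test_that("stratification commutes with estimation", {
  co <- simulate_cohort(cohort_config(n = 1000, seed = 73))
  sub <- stratum_filter(co, "tg_150_399")$data
  est_then_filter <- estimate_ldl(co, equation = "chen",
                                  override_tg_domain = TRUE)[co$tg >= 150 & co$tg < 400]
  filter_then_est <- estimate_ldl(sub, equation = "chen")
  expect_identical(est_then_filter, filter_then_est)
})

test_that("unknown strata are refused with the available list", {
  co <- data.frame(tc = 200, hdl = 50, tg = 100)
  expect_error(stratum_filter(co, "bogus"), "unknown stratum")
  expect_error(stratum_filter(co, "bogus"), "tg_150_399")
})
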