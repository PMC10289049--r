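test_that("log-normal quantile matching is exact under geometric symmetry", {
  p <- lognormal_params_from_quantiles(100, 50, 200)
  expect_equal(p$location, log(100))
  expect_equal(p$scale, log(4) / (2 * qnorm(0.75)))
  expect_equal(p$asymmetry, 1)
  # implied law reproduces the requested quantiles
  expect_equal(qlnorm(c(0.25, 0.5, 0.75), p$location, p$scale),
               c(50, 100, 200))
})

test_that("asymmetric quantiles average the one-sided scales", {
  p <- lognormal_params_from_quantiles(114, 81, 164)
  z <- qnorm(0.75)
  expect_equal(p$scale, log(164 / 81) / (2 * z))
  expect_equal(p$asymmetry, log(164 / 114) / log(114 / 81))
  # near-degenerate quantiles drive the scale to zero
  tiny <- lognormal_params_from_quantiles(100, 99.9999, 100.0001)
  expect_lt(tiny$scale, 1e-5)
})

test_that("invalid quantiles are refused", {
  expect_error(lognormal_params_from_quantiles(100, 120, 150), "q25 < median")
  expect_error(lognormal_params_from_quantiles(100, -1, 150), "q25 < median")
  expect_error(lognormal_params_from_quantiles(100, 50, 90), "q25 < median")
})

test_that("generated records satisfy the accounting identities exactly", {
  co <- simulate_cohort(cohort_config(n = 2000, seed = 81))
  expect_lt(max(abs(co$tc - co$hdl - co$vldl - co$lpa_c - co$ldl_ref)), 1e-9)
  expect_lt(max(abs(co$vldl * co$ratio - co$tg)), 1e-9)
  expect_equal(co$non_hdl, co$tc - co$hdl)
  expect_true(all(co$ratio >= 3 & co$ratio <= 13))
})

test_that("identical seed and config give a byte-identical cohort", {
  cfg <- cohort_config(n = 500, seed = 82)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # and the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_cohort(cfg))
  expect_identical(.Random.seed, before)
})

test_that("sample medians converge to the configured medians", {
  co <- simulate_cohort(cohort_config(n = 30000, seed = 83))
  expect_equal(median(co$tg), 114, tolerance = 0.03)
  expect_equal(median(co$hdl), 51, tolerance = 0.03)
  expect_equal(median(co$ldl_ref), 114, tolerance = 0.03)
  expect_equal(median(co$ratio), 5.0, tolerance = 0.03)
  expect_equal(median(co$lpa_c), 6, tolerance = 0.03)
})

test_that("covariates appear at their configured proportions", {
  co <- simulate_cohort(cohort_config(n = 30000, seed = 84))
  expect_equal(mean(co$sex == "female"), 0.537, tolerance = 0.02)
  expect_equal(mean(co$fasting == "unknown"), 0.687, tolerance = 0.02)
  expect_equal(mean(is.na(co$age)), 0.007, tolerance = 0.25)
  expect_equal(mean(co$egfr < 60), 361079 / 4939528, tolerance = 0.1)
  expect_equal(mean(co$tsh < 0.5 | co$tsh > 4.5),
               (39515 + 27350) / 4939528, tolerance = 0.15)
  ages <- co$age[!is.na(co$age)]
  expect_true(all(ages >= 0))
})

test_that("Friedewald error grows more negative with TG among low-LDL records", {
  co <- simulate_cohort(cohort_config(n = 30000, seed = 85))
  lo <- co[co$ldl_ref < 100 & co$tg < 400, ]
  err <- estimate_ldl(lo, equation = "friedewald") - lo$ldl_ref
  ct <- suppressWarnings(
    cor.test(err, lo$tg, method = "spearman", alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("invalid generator configs are refused", {
  expect_error(cohort_config(tg = c(114, 164, 81)), "q25 < median")
  expect_error(cohort_config(fasting_props = c(fasting = 0.5,
                                               non_fasting = 0.2,
                                               unknown = 0.2)),
               "sum to 1")
  expect_error(simulate_cohort(cohort_config(n = 100, ratio_tg_coupling = 2)),
               "too strong")
})
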