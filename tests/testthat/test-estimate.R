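test_that("anchored closed-form values are reproduced exactly", {
  expect_equal(estimate_ldl(200, 50, 100, "friedewald"), 130)
  expect_equal(estimate_ldl(200, 50, 100, "chen"), 125)      # 180 - 45 - 10
  expect_equal(estimate_ldl(200, 50, 100, "cordova"), 112.5) # 0.75 * 150
})

test_that("engine matches the independent transcription of every equation", {
  p <- make_panels(200, seed = 21)
  for (id in names(oracle_equations)) {
    got <- estimate_ldl(p, equation = id, override_tg_domain = TRUE)
    want <- oracle_equations[[id]](p$tc, p$hdl, p$tg)
    expect_lt(max(abs(got - want)), 1e-9, label = id)
  }
})

test_that("fixed-ratio family conserves the cholesterol accounting identity", {
  p <- make_panels(500, seed = 22)
  reg <- ldl_equations()
  for (id in reg$id[reg$family == "fixed_ratio"]) {
    k <- reg$k[reg$id == id]
    est <- estimate_ldl(p, equation = id)
    expect_equal(est + p$hdl + p$tg / k, p$tc, tolerance = 1e-12, label = id)
  }
})

test_that("fixed-ratio estimates are strictly decreasing in TG", {
  tg <- seq(10, 399, by = 1)
  for (id in c("friedewald", "delong", "vujovic")) {
    est <- estimate_ldl(rep(220, length(tg)), 55, tg, equation = id)
    expect_true(all(diff(est) < 0), label = id)
  }
})

test_that("zero-intercept linear equations are homogeneous of degree 1", {
  p <- make_panels(100, seed = 23)
  for (id in c("chen", "cordova")) {
    one <- estimate_ldl(p, equation = id)
    scaled <- estimate_ldl(p$tc * 3, p$hdl * 3, p$tg * 3, equation = id,
                           override_tg_domain = TRUE)
    expect_equal(scaled, 3 * one, tolerance = 1e-12, label = id)
  }
})

test_that("estimates are returned unclipped, negative values included", {
  est <- estimate_ldl(60, 55, 399, "friedewald") # 5 - 79.8
  expect_lt(est, 0)
})

test_that("TG domain is enforced unless overridden", {
  expect_error(estimate_ldl(200, 50, 450, "friedewald"), "friedewald")
  expect_error(estimate_ldl(200, 50, 450, "friedewald"), "450")
  expect_equal(estimate_ldl(200, 50, 450, "friedewald",
                            override_tg_domain = TRUE),
               200 - 50 - 90)
  # Sampson's published validation extends to TG 800
  expect_silent(estimate_ldl(200, 50, 450, "sampson"))
})

test_that("the composite adjustable-factor estimator dispatches on TG 400", {
  est <- estimate_ldl(c(220, 220), 50, c(399, 401), "martin_hopkins_auto")
  expect_equal(est[1], estimate_ldl(220, 50, 399, "martin_hopkins"))
  expect_equal(est[2], estimate_ldl(220, 50, 401, "martin_hopkins_extended"))
})

test_that("an all-5.0 factor table reduces bit-for-bit to Friedewald", {
  p <- make_panels(1000, seed = 24)
  flat5 <- list(variant = "standard", tg_edges = c(0, 400),
                nonhdl_edges = c(0, Inf), factors = matrix(5, 1, 1))
  expect_identical(table_factor_ldl(p, table = flat5),
                   estimate_ldl(p, equation = "friedewald"))
  flat6 <- list(variant = "standard", tg_edges = c(0, 400),
                nonhdl_edges = c(0, Inf), factors = matrix(6, 1, 1))
  expect_equal(table_factor_ldl(200, 50, 120, table = flat6), 130)
})

test_that("the packaged table route equals the two-step hand computation", {
  p <- make_panels(1000, seed = 25)
  got <- estimate_ldl(p, equation = "martin_hopkins")
  f <- martin_hopkins_factor(p$tg, p$tc - p$hdl)
  expect_lt(max(abs(got - (p$tc - p$hdl - p$tg / f))), 1e-9)
})
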