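test_that("categorization uses half-open guideline bins", {
  expect_equal(as.character(ldl_category(69.999)), "55-69")
  expect_equal(as.character(ldl_category(70)), "70-99")
  expect_equal(as.character(ldl_category(-3)), "<40")
  expect_equal(as.character(ldl_category(190)), ">=190")
  expect_equal(nlevels(ldl_category(100)), 8L)
  expect_error(ldl_category(NaN), "finite")
  expect_error(ldl_category(Inf), "finite")
})

test_that("categorization is non-decreasing", {
  set.seed(41)
  x <- sort(c(runif(500, -20, 260), 40, 55, 70, 100, 130, 160, 190))
  expect_false(is.unsorted(ldl_category(x)))
})

test_that("identical estimates give perfect concordance in every category", {
  set.seed(42)
  x <- runif(200, 10, 250)
  cc <- concordance(x, x)
  expect_equal(cc$overall, 1)
  nonempty <- cc$by_category$n > 0
  expect_true(all(cc$by_category$proportion[nonempty] == 1))
})

test_that("a four-pair example counts three matches of four", {
  # (est, ref) category pairs (0,0), (0,1), (3,3), (7,7)
  est <- c(20, 30, 80, 200)
  ref <- c(25, 45, 85, 230)
  expect_equal(concordance(est, ref)$overall, 0.75)
})

test_that("a 20-record fixture matches an exhaustive hand tally, both orientations", {
  set.seed(43)
  est <- runif(20, 20, 220)
  ref <- runif(20, 20, 220)
  # independent tally: explicit binning and loops
  bin <- function(x) {
    edges <- c(40, 55, 70, 100, 130, 160, 190)
    b <- 1L
    for (e in edges) if (x >= e) b <- b + 1L
    b
  }
  be <- vapply(est, bin, integer(1))
  br <- vapply(ref, bin, integer(1))
  expect_equal(concordance(est, ref)$overall, sum(be == br) / 20)
  for (orient in c("reference", "estimate")) {
    strat <- if (orient == "reference") br else be
    cc <- concordance(est, ref, by = orient)
    for (b in 1:8) {
      n_b <- sum(strat == b)
      hit_b <- sum(strat == b & be == br)
      expect_equal(cc$by_category$n[b], n_b)
      expect_equal(cc$by_category$proportion[b],
                   if (n_b > 0) hit_b / n_b else NA_real_,
                   label = sprintf("%s bin %d", orient, b))
    }
  }
})

test_that("overall concordance is permutation invariant and the weighted mean
           of per-category concordances", {
  set.seed(44)
  est <- runif(100, 10, 250)
  ref <- est + rnorm(100, 0, 15)
  cc <- concordance(est, ref)
  perm <- sample(100)
  expect_equal(concordance(est[perm], ref[perm])$overall, cc$overall)
  for (orient in c("reference", "estimate")) {
    bc <- concordance(est, ref, by = orient)$by_category
    keep <- bc$n > 0
    expect_equal(sum(bc$n[keep] * bc$proportion[keep]) / sum(bc$n), cc$overall)
  }
  expect_true(all(cc$by_category$proportion >= 0, na.rm = TRUE))
  expect_true(all(cc$by_category$proportion <= 1, na.rm = TRUE))
})

test_that("degenerate concordance inputs raise validation errors", {
  expect_error(concordance(1:3, 1:2), "equal length")
  expect_error(concordance(numeric(0), numeric(0)), "empty")
})
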