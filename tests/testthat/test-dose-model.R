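grid16 <- voxel_grid(c(16, 16, 10), c(1, 1, 3))

test_that("motion blur identities hold", {
  set.seed(51)
  vals <- array(runif(prod(grid16$dims), 0, 60), grid16$dims)
  d <- dose_field(vals, grid16)
  zero <- motion_model(matrix(0, 3, 3))
  expect_equal(blur_dose_for_motion(d, zero)$values, vals)

  const <- dose_field(array(42, grid16$dims), grid16)
  mm <- motion_model(rbind(c(0, 0, 0), c(2, -1, 3), c(-3, 2, -6)))
  expect_equal(blur_dose_for_motion(const, mm)$values,
               array(42, grid16$dims))

  # linear field, symmetric +/-2 mm shifts with equal weights: interior
  # voxels are unchanged (mean of symmetric shifts of a linear field)
  lin <- dose_field(array(rep(seq_len(16), 160), grid16$dims), grid16)
  sym <- motion_model(rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0)),
                      weights = c(0, 0.5, 0.5))
  out <- blur_dose_for_motion(lin, sym)$values
  expect_equal(out[3:14, , ], lin$values[3:14, , ])
  expect_error(blur_dose_for_motion(to_eqd2(const), zero), "precede")
})

test_that("EQD2 conversion follows the linear-quadratic iso-effect form", {
  g <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  mk <- function(D, n) dose_field(array(D, c(2, 2, 2)), g, n_fractions = n)
  # fixed point at 2 Gy/fraction
  expect_equal(to_eqd2(mk(10, 5))$values[1], 10)
  expect_equal(to_eqd2(mk(0, 5))$values[1], 0)
  # 60 Gy in 5 fractions, alpha/beta 10: 60 * (12 + 10) / 12 = 110
  expect_equal(to_eqd2(mk(60, 5))$values[1], 110)
  e <- to_eqd2(mk(30, 3))
  expect_identical(e$kind, "eqd2")
  expect_error(to_eqd2(e), "already")
  # monotone in D for fixed fractionation
  D <- seq(0, 80, by = 5)
  ev <- vapply(D, function(x) to_eqd2(mk(x, 5))$values[1], numeric(1))
  expect_true(all(diff(ev) > 0))
})

test_that("generalised mean identities and limits hold", {
  expect_equal(generalised_mean(c(10, 40), c(0.5, 0.5), 1), 25)
  expect_equal(generalised_mean(c(10, 40), c(0.5, 0.5), -1), 16)
  expect_equal(generalised_mean(c(30, 30, 30), c(1, 2, 3), -3), 30)
  expect_equal(generalised_mean(c(30, 30, 30), c(1, 2, 3), 2), 30)
  # weights need not be normalised
  expect_equal(generalised_mean(c(10, 40), c(2, 2), -1), 16)
  # monotone non-decreasing in a; bounded by min/max; limits at a = +/-50
  d <- c(10, 20, 40, 80)
  v <- c(1, 1, 1, 1)
  gs <- vapply(c(-50, -5, -3, -1, 1, 3, 50), function(a) {
    generalised_mean(d, v, a)
  }, numeric(1))
  expect_true(all(diff(gs) >= -1e-9))
  expect_true(all(gs >= min(d) - 1e-9 & gs <= max(d) + 1e-9))
  expect_equal(gs[1], min(d), tolerance = 0.05)
  expect_equal(gs[7], max(d), tolerance = 0.05)
  expect_error(generalised_mean(c(0, 10), c(0.5, 0.5), -1), "non-positive")
  expect_true(is.na(generalised_mean(c(10, 20), c(0, 0), -1)))
})

test_that("weighted SD and cold-spot fraction match hand arithmetic", {
  expect_equal(weighted_sd(c(20, 40), c(0.25, 0.75)), sqrt(75))
  expect_equal(weighted_sd(c(7, 7, 7), c(1, 1, 1)), 0)
  expect_equal(fraction_below(c(10, 50), c(0.5, 0.5), 30), 0.5)
  expect_equal(fraction_below(c(40, 50), c(1, 1), 30), 0)
  expect_equal(fraction_below(c(10, 20), c(1, 1), 30), 1)
  expect_true(is.na(fraction_below(c(10, 20), c(0, 0), 30)))
})

test_that("exponent diagnostic tests the stated candidates and flags skew", {
  # cohort with graded cold-spot fractions (a few patients much colder):
  # the generalised-mean distribution grows a progressively longer tail as
  # a becomes more negative, so the computed skewness increases
  set.seed(99)
  cohort <- lapply(1:30, function(i) {
    w <- rbeta(1, 0.5, 8) * 0.4
    list(d = c(runif(1, 2, 8), runif(1, 45, 55)), v = c(w, 1 - w))
  })
  diag <- exponent_diagnostic(cohort, a_candidates = -1:-5)
  expect_identical(diag$a, -1:-5)
  expect_true(all(diff(diag$skewness) > 0))
  # with a +/-2 bound the scan stops before -4 (skew 2.06): recommends -3,
  # mirroring the shape of the published exponent choice
  diag2 <- exponent_diagnostic(cohort, a_candidates = -1:-5, skew_bound = 2)
  expect_identical(attr(diag2, "recommended_a"), -3L)
  # identical patients: skewness undefined, flagged as NA
  same <- lapply(1:5, function(i) list(d = c(30, 40), v = c(1, 1)))
  d2 <- exponent_diagnostic(same)
  expect_true(all(is.na(d2$skewness)))
  expect_error(exponent_diagnostic(same[1:2]), "at least 3")
})
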