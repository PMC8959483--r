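fake_fit <- function(b2, b3, v22 = 0.01, v33 = 0.02, v23 = 0.002) {
  V <- matrix(c(v22, v23, v23, v33), 2, 2,
              dimnames = list(c(".density", ".inter"),
                              c(".density", ".inter")))
  structure(list(coefficients = c(.density = b2, .inter = b3), vcov = V),
            class = "cox_fit")
}

test_that("contrast curves follow the interaction algebra", {
  f <- fake_fit(0.2, 0.5)
  # hand case: b2 = 0.2, b3 = 0.5, dose 1, delta = 2 -> ln HR = 1.4
  cc <- contrast_curve(f, density_grid = 2, dose_value = 1, density_mean = 0)
  expect_equal(cc$ln_hr, 1.4)
  # zero at the mean density, with zero-width CI
  cc0 <- contrast_curve(f, density_grid = 5, dose_value = 3, density_mean = 5)
  expect_equal(cc0$ln_hr, 0)
  expect_equal(cc0$ci_lo, 0)
  expect_equal(cc0$ci_hi, 0)
  # b3 = 0: straight line of slope b2, independent of the dose level
  f0 <- fake_fit(0.3, 0)
  g <- seq(-2, 2, by = 0.5)
  c1 <- contrast_curve(f0, g, dose_value = 10, density_mean = 0)
  c2 <- contrast_curve(f0, g, dose_value = -4, density_mean = 0)
  expect_equal(c1$ln_hr, 0.3 * g)
  expect_equal(c1$ln_hr, c2$ln_hr)
  # delta-method variance matches the written formula
  cc2 <- contrast_curve(f, density_grid = 3, dose_value = 2, density_mean = 1)
  v <- 2^2 * (0.01 + 4 * 0.02 + 2 * 2 * 0.002)
  expect_equal(cc2$ci_hi - cc2$ln_hr, 1.96 * sqrt(v))
})

test_that("curves at different dose levels fan about the mean-density pivot", {
  f <- fake_fit(0.2, 0.5)
  g <- seq(-3, 3, by = 1)
  lv <- lapply(c(1, 5, 9), function(D) {
    contrast_curve(f, g, D, density_mean = 0)$ln_hr
  })
  at_mean <- vapply(lv, function(v) v[g == 0], numeric(1))
  expect_equal(at_mean, rep(0, 3))
  # sign flip of b3 mirrors the fan about the b3 = 0 line
  fneg <- fake_fit(0.2, -0.5)
  base <- contrast_curve(fake_fit(0.2, 0), g, 5, 0)$ln_hr
  up <- contrast_curve(f, g, 5, 0)$ln_hr
  dn <- contrast_curve(fneg, g, 5, 0)$ln_hr
  expect_equal(up - base, base - dn)
})

test_that("spearman matches manual rank computation, ties included", {
  expect_equal(spearman(1:8, (1:8)^3), 1)
  expect_equal(spearman(1:8, -(1:8)), -1)
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 8)
  rx <- rank(x)                                  # average ranks for ties
  ry <- rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman(x, y), manual)
  expect_warning(out <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("confounding report covers the standard metric pairs", {
  set.seed(81)
  n <- 40
  vol <- runif(n, 1, 30)
  mot <- runif(n, 0, 15)
  gtv_dose <- runif(n, 100, 120)
  dep <- vol^2 + rnorm(n, 0, 1)                 # dose metric driven by volume
  ind <- rnorm(n)
  rep_df <- confounding_report(
    density_values = list(mean = rnorm(n), sd = ind),
    dose_values = list(dose_sd = dep, gen_mean = rnorm(n)),
    volume = vol, motion = mot, mean_gtv_dose = gtv_dose)
  expect_identical(nrow(rep_df), 2L * 3L + 2L * 2L)
  got <- rep_df$rho[rep_df$metric == "dose_sd" & rep_df$against == "volume"]
  expect_gt(abs(got), 0.9)
  ind_rho <- rep_df$rho[rep_df$metric == "gen_mean" &
                        rep_df$against == "volume"]
  expect_lt(abs(ind_rho), 0.4)
  expect_identical(sort(unique(rep_df$against[rep_df$kind == "dose"])),
                   c("mean_gtv_dose", "motion", "volume"))
  expect_identical(sort(unique(rep_df$against[rep_df$kind == "density"])),
                   c("motion", "volume"))
})

test_that("group mean curves recover group structure", {
  m <- rbind(c(1, 1, 1), c(1, 1, 1), c(4, 4, 4), c(4, 4, NA))
  attr(m, "distances") <- c(0.1, 0.2, 0.3)
  gm <- group_mean_curves(m, c("a", "a", "b", "b"))
  a <- gm[gm$group == "a", ]
  expect_equal(a$mean, rep(1, 3))
  expect_equal(a$ci_hi - a$ci_lo, rep(0, 3))     # identical patients
  b <- gm[gm$group == "b", ]
  expect_equal(b$mean, c(4, 4, 4))
  expect_true(is.na(b$ci_lo[3]))                 # singleton annulus: no CI
  # seeded groups match direct per-annulus averaging
  set.seed(82)
  mm <- matrix(rnorm(60), 10, 6)
  attr(mm, "distances") <- seq(0.05, 0.55, by = 0.1)
  grp <- rep(c("x", "y"), each = 5)
  gmm <- group_mean_curves(mm, grp)
  expect_equal(gmm$mean[gmm$group == "x"], colMeans(mm[1:5, ]))
  expect_equal(gmm$mean[gmm$group == "y"], colMeans(mm[6:10, ]))
})

test_that("plot methods run on a null device", {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  f <- fake_fit(0.2, 0.5)
  cc <- contrast_curve(f, seq(-2, 2, 0.5), 1, 0)
  expect_invisible(plot(cc))
  m <- structure(
    list(p_values = matrix(runif(25, 0.01, 1), 5, 5),
         n_used = matrix(20L, 5, 5), metric_pair = c("mean", "dose_sd"),
         density_distances = seq(0.05, 0.45, 0.1),
         dose_distances = seq(0.05, 0.45, 0.1), min_events = 10L),
    class = "interaction_map")
  expect_invisible(plot(m))
})
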