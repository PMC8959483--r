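test_that("patient generation is deterministic and respects nesting", {
  cfg <- fast_cohort_config()
  p1 <- generate_patient(cfg, 123L)
  p2 <- generate_patient(cfg, 123L)
  expect_identical(p1$phases[[1]], p2$phases[[1]])
  expect_identical(p1$dose$values, p2$dose$values)
  expect_identical(p1$covariates, p2$covariates)
  p3 <- generate_patient(cfg, 124L)
  expect_false(identical(p1$phases[[1]], p3$phases[[1]]))
  # mask nesting: body > lung > gtv
  expect_true(all(p1$gtv <= p1$lung))
  expect_true(all(p1$lung <= p1$body))
  expect_true(all(p1$dose$values >= 0))
  # oversized tumour rejected
  tiny <- cohort_config(n_patients = 1, dims = c(20L, 20L, 10L),
                        spacing = c(1, 1, 3),
                        volume_range_cc = c(30, 34),
                        density_window = c(-0.5, 0.5),
                        dose_window = c(0.5, 1.5),
                        planted = list(density_stat = "mean",
                                       density_cm = 0.05,
                                       dose_stat = "dose_sd",
                                       dose_cm = 1.05,
                                       b1 = 0, b2 = 0, b3 = 0))
  expect_error(generate_patient(tiny, 1L), "exceeds grid")
})

test_that("zero heterogeneity gives zero density SD inside the tumour", {
  cfg <- fast_cohort_config(heterogeneity_sd = 0, image_noise_sd = 0)
  pat <- generate_patient(cfg, 55L)
  labels <- annulus_labels(pat$sdm, cfg$density_window)
  h <- build_radial_histogram(pat$phases[[1]], labels, pat$lung | pat$gtv,
                              density_bin_edges(), pat$grid)
  sd_curve <- annulus_stats(h, "sd")
  interior <- sd_curve$distances < 0 & sd_curve$valid
  expect_true(any(interior))
  expect_true(all(sd_curve$values[interior] == 0))
})

test_that("doubling penumbra steepness halves the 80-20 fall-off distance", {
  base_cfg <- fast_cohort_config(incidental_fraction = c(0, 0),
                                 cold_spot_prob = 0)
  steep_cfg <- fast_cohort_config(incidental_fraction = c(0, 0),
                                  cold_spot_prob = 0,
                                  penumbra_steepness = 8)
  fall_off <- function(cfg) {
    pat <- generate_patient(cfg, 77L)        # same seed: same geometry
    d <- pat$sdm$values
    rx <- cfg$prescription_gy
    # mean dose in fine shells outside the border
    shells <- seq(0, 25, by = 0.5)
    mu <- vapply(shells[-1], function(hi) {
      lo <- hi - 0.5
      mean(pat$dose$values[d >= lo & d < hi])
    }, numeric(1))
    mid <- shells[-1] - 0.25
    d80 <- stats::approx(mu, mid, xout = 0.8 * rx)$y
    d20 <- stats::approx(mu, mid, xout = 0.2 * rx)$y
    d20 - d80
  }
  w1 <- fall_off(base_cfg)
  w2 <- fall_off(steep_cfg)
  expect_equal(w1 / w2, 2, tolerance = 0.15)
})

test_that("cohort simulation is deterministic and closes the loop", {
  cfg <- fast_cohort_config(n_patients = 10L)
  c1 <- simulate_cohort(cfg, seed = 5L)
  c2 <- simulate_cohort(cfg, seed = 5L)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$density_curves$mean, c2$density_curves$mean)
  gt <- c1$ground_truth
  # planted values are exactly the pipeline statistics at the planted annuli
  expect_identical(gt$density_values,
                   c1$density_curves$mean[, gt$density_index])
  expect_identical(gt$dose_values,
                   c1$dose_curves$dose_sd[, gt$dose_index])
  # the stored log hazard reconstructs from the stored pieces
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  pl <- gt$planted
  eta_imaging <- pl$b1 * zs(gt$dose_values) + pl$b2 * zs(gt$density_values) +
    pl$b3 * zs(gt$density_values) * zs(gt$dose_values)
  cb <- cfg$clinical_betas
  r <- c1$records
  eta_clin <- cb[["age"]] * zs(r$age) + cb[["sex_male"]] * r$sex_male +
    cb[["log_volume"]] * zs(r$log_volume_cc) +
    cb[["upper_lobe"]] * r$upper_lobe + cb[["motion"]] * zs(r$motion_mm)
  expect_equal(gt$eta, eta_imaging + eta_clin)
})

test_that("null imaging effects leave outcomes unrelated to imaging", {
  cfg <- fast_cohort_config(
    n_patients = 40L,
    planted = list(density_stat = "mean", density_cm = 0.05,
                   dose_stat = "dose_sd", dose_cm = 2.05,
                   b1 = 0, b2 = 0, b3 = 0),
    clinical_betas = c(age = 0, sex_male = 0, log_volume = 0,
                       upper_lobe = 0, motion = 0))
  co <- simulate_cohort(cfg, seed = 6L)
  gt <- co$ground_truth
  expect_equal(unname(gt$eta), rep(0, 40))
  rho <- suppressWarnings(
    spearman(co$records$time, gt$density_values * gt$dose_values))
  expect_lt(abs(rho), 0.45)
})

test_that("event fraction hits the 17% target at n = 200 (default world)", {
  co <- simulate_cohort(cohort_config(n_patients = 200L, n_phases = 1L),
                        seed = 2026L)
  frac <- mean(co$records$event)
  expect_lt(abs(frac - 0.17), 0.05)
  # survival times positive, censoring present
  expect_true(all(co$records$time > 0))
  expect_true(any(co$records$event == 0))
  # tumour volumes live in the stated range
  vol <- exp(co$records$log_volume_cc)
  expect_true(all(vol > 0.2 & vol < 40))
})

test_that("stronger planted interactions raise the LR statistic at the planted cell", {
  lr_at_plant <- function(b3, seed) {
    cfg <- fast_cohort_config(
      n_patients = 80L,
      planted = list(density_stat = "mean", density_cm = 0.05,
                     dose_stat = "dose_sd", dose_cm = 2.05,
                     b1 = 0.2, b2 = 0.2, b3 = b3))
    co <- simulate_cohort(cfg, seed = seed)
    gt <- co$ground_truth
    df <- co$records
    df$.density <- gt$density_values
    df$.dose <- gt$dose_values
    df$.inter <- df$.density * df$.dose
    full <- fit_cox(df, c(co$covariates, ".density", ".dose", ".inter"))
    red <- fit_cox(df, c(co$covariates, ".density", ".dose"))
    lr_test(full, red)$statistic
  }
  # paired by seed: identical patients and event-time draws, only the
  # planted effect differs
  for (s in c(301L, 302L)) {
    expect_gt(lr_at_plant(1.2, s), lr_at_plant(0, s))
  }
})
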