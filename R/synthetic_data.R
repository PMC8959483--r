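#' Synthetic cohort configuration
#'
#' Defaults describe the emulated clinical setting: ~200 early-stage lung
#' cancer patients treated with 60 Gy in 5 fractions, tumour volumes
#' 0.3-34 cc, ~17% distant-metastasis rate, and a planted interaction
#' between a density statistic at one radial location and a dose statistic
#' at another. The generator's dose model is stylised SABR: a uniform
#' prescription core out to a small margin, a sigmoidal radial penumbra,
#' an exponentially decaying, angularly modulated incidental-dose tail,
#' and optional angular cold-spot sectors.
#'
#' @param n_patients cohort size (default 200).
#' @param dims,spacing grid (default 64 x 64 x 44 voxels at 1 x 1 x 3 mm,
#'   mirroring CT slice anisotropy; deep enough in z that the 4-cm dose
#'   shell of the largest tumours stays inside the synthetic body).
#' @param volume_range_cc tumour volume range, log-uniform (0.3-34 cc).
#' @param tumour_mean_hu mean tumour density (HU).
#' @param heterogeneity_sd SD of within-tumour density texture (HU).
#' @param image_noise_sd per-phase acquisition noise inside the tumour and
#'   lung (HU).
#' @param lung_hu,lung_noise_sd lung background level and texture (HU).
#' @param peritumour_amplitude_hu,peritumour_gradient peak density excess
#'   at the tumour surface and its linear decay rate (HU/mm).
#' @param prescription_gy,n_fractions,alpha_beta fractionation scheme.
#' @param margin_mm distance from the tumour border to the penumbra
#'   midpoint (PTV-like margin).
#' @param penumbra_steepness maximum dose fall-off slope (Gy/mm).
#' @param incidental_fraction range of the incidental-dose amplitude as a
#'   fraction of prescription; `incidental_tau_mm` its decay length.
#' @param cold_spot_prob,cold_spot_depth,cold_spot_width_deg probability,
#'   depth range (fractional) and angular width of a cold sector.
#' @param motion_meanlog,motion_sdlog,motion_cap_mm log-normal motion
#'   amplitude distribution (median ~5 mm) and cap.
#' @param n_phases respiratory phases to synthesise (>= 3 enables phase
#'   selection; 1 is a fast path that uses the reference phase directly).
#' @param density_window,dose_window radial windows in cm.
#' @param sigma_mm curve smoothing SD.
#' @param gen_mean_a,dose_threshold dose-metric settings.
#' @param planted list: `density_stat`, `density_cm`, `dose_stat`,
#'   `dose_cm`, `b1` (dose), `b2` (density), `b3` (interaction) - the
#'   coefficients act on cohort-standardised pipeline statistics.
#' @param clinical_betas named effects of the clinical covariates on the
#'   log hazard (standardised scales).
#' @param baseline_rate exponential baseline hazard (events/month).
#' @param event_fraction target event fraction (0.17).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          dims = c(64L, 64L, 44L),
                          spacing = c(1, 1, 3),
                          volume_range_cc = c(0.3, 34),
                          tumour_mean_hu = 20,
                          heterogeneity_sd = 60,
                          image_noise_sd = 20,
                          lung_hu = -800,
                          lung_noise_sd = 30,
                          peritumour_amplitude_hu = 500,
                          peritumour_gradient = 50,
                          prescription_gy = 60,
                          n_fractions = 5L,
                          alpha_beta = 10,
                          margin_mm = 5,
                          penumbra_steepness = 4,
                          incidental_fraction = c(0.15, 0.4),
                          incidental_tau_mm = 25,
                          cold_spot_prob = 0.3,
                          cold_spot_depth = c(0.2, 0.6),
                          cold_spot_width_deg = 60,
                          motion_meanlog = log(5),
                          motion_sdlog = 0.8,
                          motion_cap_mm = 34,
                          n_phases = 5L,
                          density_window = c(-0.5, 2),
                          dose_window = c(0.5, 4),
                          sigma_mm = 1.5,
                          gen_mean_a = -3,
                          dose_threshold = 30,
                          planted = list(density_stat = "mean",
                                         density_cm = 0.05,
                                         dose_stat = "dose_sd",
                                         dose_cm = 3.05,
                                         b1 = 0.24, b2 = 0.19, b3 = 0.47),
                          clinical_betas = c(age = 0.1, sex_male = 0.1,
                                             log_volume = 0.3,
                                             upper_lobe = -0.1,
                                             motion = 0.1),
                          baseline_rate = 0.01,
                          event_fraction = 0.17) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1L,
            all(cfg$spacing > 0),
            cfg$volume_range_cc[1] > 0,
            cfg$heterogeneity_sd >= 0,
            cfg$prescription_gy > 0, cfg$n_fractions >= 1L,
            cfg$penumbra_steepness > 0,
            cfg$event_fraction > 0, cfg$event_fraction < 1)
  if (cfg$planted$density_cm < cfg$density_window[1] ||
      cfg$planted$density_cm > cfg$density_window[2] ||
      cfg$planted$dose_cm < cfg$dose_window[1] ||
      cfg$planted$dose_cm > cfg$dose_window[2]) {
    stop("planted distances must lie inside the respective windows")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# voxel-centre coordinates (mm) relative to grid centre, one vector per axis
axis_coords <- function(grid) {
  lapply(1:3, function(k) {
    (seq_len(grid$dims[k]) - (grid$dims[k] + 1) / 2) * grid$spacing[k]
  })
}

# ellipsoid membership on the grid: sum((x - centre)^2 / axes^2) <= 1
ellipsoid_mask <- function(grid, centre, axes) {
  cc <- axis_coords(grid)
  q1 <- ((cc[[1]] - centre[1]) / axes[1])^2
  q2 <- ((cc[[2]] - centre[2]) / axes[2])^2
  q3 <- ((cc[[3]] - centre[3]) / axes[3])^2
  outer(outer(q1, q2, "+"), q3, "+") <= 1
}

#' Generate one synthetic patient
#'
#' Ellipsoidal tumour of log-uniformly sampled volume with internal HU
#' texture; lung background with a peritumoural density ramp decaying
#' linearly from the tumour surface; nested body > lung > GTV masks;
#' SABR-like physical dose; sinusoidal per-phase translations (reference
#' phase first, translation zero). Phase images are the clean tissue field
#' shifted by the phase translation (tumour moving against the fixed
#' reference GTV) plus independent acquisition noise.
#'
#' @param config a [cohort_config()].
#' @param patient_seed integer seed; same (config, seed) reproduces the
#'   patient exactly.
#' @return List: `phases` (list of HU arrays), `gtv`, `lung`, `body`,
#'   `dose` (physical `dose_field`), `motion` (a [motion_model()]),
#'   `covariates`, `grid`, `patient_seed`.
#' @export
generate_patient <- function(config, patient_seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(patient_seed)
  grid <- voxel_grid(config$dims, config$spacing)
  extent <- grid$dims * grid$spacing
  cc <- axis_coords(grid)

  vol_cc <- exp(stats::runif(1, log(config$volume_range_cc[1]),
                             log(config$volume_range_cc[2])))
  r_mm <- (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)
  # mild ellipticity; the range keeps the largest stated tumour volume
  # inside the default grid along every axis
  shape <- stats::runif(3, 0.9, 1.12)
  shape <- shape / prod(shape)^(1 / 3)
  axes <- r_mm * shape
  if (any(axes + config$margin_mm + 2 > extent / 2)) {
    stop("tumour exceeds grid: enlarge dims or shrink volume range")
  }
  centre <- c(0, 0, 0)
  gtv <- ellipsoid_mask(grid, centre, axes)
  lung <- ellipsoid_mask(grid, c(0, 0, 0), 0.46 * extent) | gtv
  body <- ellipsoid_mask(grid, c(0, 0, 0), 0.49 * extent) | lung

  sdm <- signed_distance_map(gtv, grid, source_mask_id = "gtv")
  d <- sdm$values

  # clean tissue field (HU), before acquisition noise
  clean <- array(40, grid$dims)                       # soft tissue
  clean[!body] <- -1000                               # air
  clean[lung] <- config$lung_hu +
    stats::rnorm(sum(lung), 0, config$lung_noise_sd)
  amp <- config$peritumour_amplitude_hu * stats::runif(1, 0.5, 1.5)
  peri <- lung & !gtv & d > 0
  clean[peri] <- clean[peri] +
    pmax(0, amp - config$peritumour_gradient * d[peri])
  tum_mu <- config$tumour_mean_hu + stats::rnorm(1, 0, 20)
  clean[gtv] <- tum_mu + stats::rnorm(sum(gtv), 0, config$heterogeneity_sd)

  # motion: mostly cranio-caudal, sinusoidal over the cycle, reference first
  amp_mm <- min(stats::rlnorm(1, config$motion_meanlog, config$motion_sdlog),
                config$motion_cap_mm)
  dir <- c(stats::rnorm(2, 0, 0.15), 1)
  dir <- dir / sqrt(sum(dir^2))
  ph <- seq_len(config$n_phases)
  disp <- amp_mm * (1 - cos(2 * pi * (ph - 1) / config$n_phases)) / 2
  translations <- outer(disp, dir)
  motion <- motion_model(translations, reference = 1L)

  phases <- lapply(ph, function(p) {
    img <- if (disp[p] == 0) clean else {
      trilinear_shift(clean, grid, translations[p, ])
    }
    if (config$image_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, config$image_noise_sd)
    }
    img
  })

  # stylised SABR dose: uniform core, sigmoidal penumbra, incidental tail
  rx <- config$prescription_gy
  steep <- config$penumbra_steepness * stats::runif(1, 0.7, 1.4)
  k <- 4 * steep / rx
  marg <- config$margin_mm + stats::runif(1, -1, 2)
  dose_v <- rx * stats::plogis(k * (marg - d))
  inc_amp <- stats::runif(1, config$incidental_fraction[1],
                          config$incidental_fraction[2])
  phi <- atan2(
    rep(cc[[2]], each = grid$dims[1]),
    rep(cc[[1]], times = grid$dims[2]))
  phi <- array(rep(phi, times = grid$dims[3]), grid$dims)
  phi1 <- stats::runif(1, -pi, pi)
  # angular modulation whose amplitude varies with radius (period ~1-3 cm,
  # random phase per patient): beam arrangement and anatomy give real dose
  # fields radial texture, and without it the per-annulus dose-SD curve
  # would be one patient scalar times a shared profile, making radial
  # locations unidentifiable
  modamp <- stats::runif(1, 0.2, 0.8)
  omr <- stats::runif(1, 0.2, 0.5)        # rad/mm
  psr <- stats::runif(1, -pi, pi)
  m_of_d <- modamp * (0.55 + 0.45 * sin(omr * d + psr))
  tail_mod <- 1 + m_of_d * cos(phi - phi1)
  out_core <- d > marg
  dose_v[out_core] <- pmax(
    dose_v[out_core],
    rx * inc_amp * exp(-(d[out_core] - marg) / config$incidental_tau_mm) *
      tail_mod[out_core])
  if (stats::runif(1) < config$cold_spot_prob) {
    depth <- stats::runif(1, config$cold_spot_depth[1],
                          config$cold_spot_depth[2])
    phi0 <- stats::runif(1, -pi, pi)
    halfw <- config$cold_spot_width_deg * pi / 360
    ang <- abs(atan2(sin(phi - phi0), cos(phi - phi0)))
    sector <- ang < halfw & d > 2
    dose_v[sector] <- dose_v[sector] * (1 - depth)
  }
  dose <- dose_field(dose_v, grid, kind = "physical",
                     n_fractions = config$n_fractions,
                     alpha_beta = config$alpha_beta)

  covariates <- list(
    age = round(min(max(stats::rnorm(1, 76, 8), 45), 93)),
    sex_male = stats::rbinom(1, 1, 0.51),
    upper_lobe = stats::rbinom(1, 1, 0.67),
    volume_cc = sum(gtv) * grid$voxel_volume / 1000,
    motion_mm = amp_mm)

  list(phases = phases, gtv = gtv, lung = lung, body = body,
       dose = dose, motion = motion, sdm = sdm,
       covariates = covariates, grid = grid, patient_seed = patient_seed)
}

# run one generated patient through the density and dose pipelines
patient_curves <- function(pat, config) {
  grid <- pat$grid
  labels_d <- annulus_labels(pat$sdm, config$density_window)
  labels_o <- annulus_labels(pat$sdm, config$dose_window)
  restrict_d <- pat$lung | pat$gtv

  hists <- lapply(pat$phases, function(img) {
    build_radial_histogram(img, labels_d, restrict_d, density_bin_edges(),
                           grid, restrict_mask_id = "lung+gtv")
  })
  if (length(hists) >= 3L) {
    sel <- select_optimal_phase(hists)
    h_opt <- hists[[sel$phase_index]]
    phase_index <- sel$phase_index
  } else {
    h_opt <- hists[[1]]
    phase_index <- 1L
  }

  dens <- lapply(density_statistics(), function(s) {
    gaussian_smooth(annulus_stats(h_opt, s,
                                  patient_id = as.character(pat$patient_seed)),
                    config$sigma_mm)
  })
  names(dens) <- density_statistics()

  dose <- pat$dose
  if (length(pat$phases) > 1L) dose <- blur_dose_for_motion(dose, pat$motion)
  dose <- to_eqd2(dose)
  h_dose <- build_radial_histogram(dose$values, labels_o, pat$body,
                                   dose_bin_edges(), grid,
                                   restrict_mask_id = "body")
  dosec <- lapply(dose_statistics(), function(s) {
    gaussian_smooth(annulus_stats(h_dose, s, a = config$gen_mean_a,
                                  threshold = config$dose_threshold,
                                  patient_id = as.character(pat$patient_seed)),
                    config$sigma_mm)
  })
  names(dosec) <- dose_statistics()

  list(density = dens, dose = dosec, phase_index = phase_index,
       mean_gtv_dose = mean(dose$values[pat$gtv]))
}

#' Survival outcomes with a planted proportional-hazards structure
#'
#' Event times are exponential with rate `baseline_rate * exp(eta)`.
#' Censoring is uniform on `(0, c)` with `c` solved numerically on the
#' drawn event times so that the expected event fraction matches the
#' configured target.
#'
#' @param eta per-patient log relative hazard.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return Data frame `(time, event)` with attribute `censor_max`.
#' @export
generate_outcomes <- function(eta, config, seed) {
  set.seed(seed)
  n <- length(eta)
  rate <- config$baseline_rate * exp(eta)
  t_event <- stats::rexp(n) / rate
  target <- config$event_fraction
  f <- function(cmax) mean(pmax(0, 1 - t_event / cmax)) - target
  hi <- max(t_event) * 1e3
  cmax <- if (f(hi) < 0) hi else {
    stats::uniroot(f, c(min(t_event) * 1e-3, hi), tol = 1e-8)$root
  }
  cens <- stats::runif(n, 0, cmax)
  out <- data.frame(time = pmin(t_event, cens),
                    event = as.integer(t_event <= cens))
  attr(out, "censor_max") <- cmax
  out
}

#' Simulate a complete synthetic cohort through the real pipeline
#'
#' Generates every patient, runs the density and dose pipelines (phase
#' selection when `n_phases >= 3`, motion blurring, EQD2 conversion,
#' radial histograms, smoothed summary curves), standardises the planted
#' statistics across the cohort, builds the planted log hazard, and draws
#' survival outcomes. The hazard uses the pipeline-derived statistics, not
#' latent generator parameters, so recovering the planted interaction is a
#' true end-to-end test.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed for the cohort.
#' @return A list of class `synthetic_cohort`: `records` (clinical table
#'   with `time`, `event`, covariates), `covariates` (names for
#'   modelling), `density_curves` and `dose_curves` (named lists of
#'   patients x annuli matrices), `phase_selected`, `mean_gtv_dose`,
#'   `ground_truth` (planted indices, z-values, eta), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_patients
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  outcome_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  dens_curves <- rep(list(vector("list", n)), length(density_statistics()))
  names(dens_curves) <- density_statistics()
  dose_curves <- rep(list(vector("list", n)), length(dose_statistics()))
  names(dose_curves) <- dose_statistics()
  cov_rows <- vector("list", n)
  phase_sel <- integer(n)
  mean_gtv_dose <- numeric(n)

  for (i in seq_len(n)) {
    pat <- generate_patient(config, patient_seeds[i])
    pc <- patient_curves(pat, config)
    for (s in density_statistics()) dens_curves[[s]][[i]] <- pc$density[[s]]
    for (s in dose_statistics()) dose_curves[[s]][[i]] <- pc$dose[[s]]
    cov_rows[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i),
      age = pat$covariates$age,
      sex_male = pat$covariates$sex_male,
      upper_lobe = pat$covariates$upper_lobe,
      log_volume_cc = log(pat$covariates$volume_cc),
      motion_mm = pat$covariates$motion_mm)
    phase_sel[i] <- pc$phase_index
    mean_gtv_dose[i] <- pc$mean_gtv_dose
  }
  dens_mats <- lapply(dens_curves, curve_matrix)
  dose_mats <- lapply(dose_curves, curve_matrix)
  clin <- do.call(rbind, cov_rows)

  pl <- config$planted
  di <- which.min(abs(attr(dens_mats[[pl$density_stat]], "distances") -
                      pl$density_cm))
  oi <- which.min(abs(attr(dose_mats[[pl$dose_stat]], "distances") -
                      pl$dose_cm))
  dens_v <- dens_mats[[pl$density_stat]][, di]
  dose_v <- dose_mats[[pl$dose_stat]][, oi]
  if (anyNA(dens_v) || anyNA(dose_v)) {
    warning("planted statistic missing for some patients; using cohort mean")
    dens_v[is.na(dens_v)] <- mean(dens_v, na.rm = TRUE)
    dose_v[is.na(dose_v)] <- mean(dose_v, na.rm = TRUE)
  }
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  z_dens <- zs(dens_v)
  z_dose <- zs(dose_v)
  cb <- config$clinical_betas
  eta_clin <- cb[["age"]] * zs(clin$age) +
    cb[["sex_male"]] * clin$sex_male +
    cb[["log_volume"]] * zs(clin$log_volume_cc) +
    cb[["upper_lobe"]] * clin$upper_lobe +
    cb[["motion"]] * zs(clin$motion_mm)
  eta <- pl$b1 * z_dose + pl$b2 * z_dens + pl$b3 * z_dens * z_dose + eta_clin
  surv <- generate_outcomes(eta, config, outcome_seed)

  records <- cbind(clin[, "patient_id", drop = FALSE], surv,
                   clin[, -1, drop = FALSE])
  structure(
    list(records = records,
         covariates = c("age", "sex_male", "upper_lobe",
                        "log_volume_cc", "motion_mm"),
         density_curves = dens_mats,
         dose_curves = dose_mats,
         phase_selected = phase_sel,
         mean_gtv_dose = mean_gtv_dose,
         ground_truth = list(
           planted = pl,
           density_index = di, dose_index = oi,
           density_values = dens_v, dose_values = dose_v,
           z_density = z_dens, z_dose = z_dose,
           eta = eta, censor_max = attr(surv, "censor_max")),
         config = config, seed = as.integer(seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d patients, %d events (%.0f%%), seed %d\n",
    nrow(x$records), sum(x$records$event),
    100 * mean(x$records$event), x$seed))
  invisible(x)
}
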