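#' Per-patient mean of a smoothed curve over a radial interval
#'
#' Unweighted mean of the curve over the annuli whose centres fall in the
#' closed interval (cm). Patients invalid at every annulus of the interval
#' get `NA`.
#'
#' @param mat patients x annuli matrix from [curve_matrix()].
#' @param interval numeric length 2, closed interval in cm.
#' @return Numeric vector, one value per patient.
#' @export
extract_region_values <- function(mat, interval) {
  d <- attr(mat, "distances")
  stopifnot(!is.null(d), length(interval) == 2L)
  keep <- d >= interval[1] - 1e-9 & d <= interval[2] + 1e-9
  if (!any(keep)) stop("no annulus centres fall inside the interval")
  sub <- mat[, keep, drop = FALSE]
  out <- rowMeans(sub, na.rm = TRUE)
  out[rowSums(!is.na(sub)) == 0L] <- NA_real_
  out
}

#' Conditional log transform for heavily skewed region values
#'
#' Applies `log` iff the values are strictly positive, their skewness
#' magnitude exceeds `skew_bound` (default 3), and the transform actually
#' reduces that magnitude. Vectors containing non-positive values are
#' returned untouched with a warning when they are skewed enough to
#' qualify.
#'
#' @param values numeric vector.
#' @param skew_bound skewness magnitude that triggers the transform.
#' @return List: `values` (possibly logged), `applied` (flag),
#'   `skewness_before`, `skewness_after`.
#' @export
maybe_log_transform <- function(values, skew_bound = 3) {
  s0 <- sample_skewness(values)
  out <- list(values = values, applied = FALSE,
              skewness_before = s0, skewness_after = s0)
  if (is.na(s0) || abs(s0) <= skew_bound) return(out)
  if (any(values <= 0, na.rm = TRUE)) {
    warning("skewed values contain non-positive entries; log transform skipped")
    return(out)
  }
  s1 <- sample_skewness(log(values))
  if (!is.na(s1) && abs(s1) < abs(s0)) {
    out$values <- log(values)
    out$applied <- TRUE
    out$skewness_after <- s1
  }
  out
}

#' Standardise values for coefficient reporting
#'
#' Centre to mean zero and scale to unit sample variance (n - 1). Used
#' only when reporting coefficients, never when mapping or computing
#' C-indices.
#'
#' @param values numeric vector with positive variance.
#' @return Standardised vector.
#' @export
standardise_for_report <- function(values) {
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    stop("zero variance: values should have been screened out")
  }
  (values - mean(values, na.rm = TRUE)) / s
}

#' Bootstrap stability analysis of a region's interaction model
#'
#' Draws `n_resamples` patient resamples (with replacement, cohort size).
#' On each resample the interaction model (clinical covariates + density +
#' dose + density:dose) and its no-interaction reduction are fitted; the
#' likelihood-ratio significance of the interaction is recorded, and the
#' resample-fitted interaction model is scored by Harrell's C-index on the
#' ORIGINAL cohort. Resamples without events are redrawn (counted).
#'
#' @param records complete-case data frame with `time`, `event`, clinical
#'   covariates.
#' @param density_values,dose_values per-patient region values (no NA).
#' @param covariates clinical covariate names.
#' @param n_resamples number of bootstrap resamples (default 500).
#' @param seed integer RNG seed; same seed gives a bit-identical summary.
#' @param alpha LR significance level (default 0.05).
#' @param time,event survival column names.
#' @return An object of class `bootstrap_summary`: `n_resamples`,
#'   `c_index_median`, `c_index_ci`, `lr_significant_fraction` (percent),
#'   `b3_ci` (percentile), `stable` (same-sign CI), `n_redrawn`,
#'   `n_failed`, and the raw `c_index` / `b3` / `p_value` vectors.
#' @export
bootstrap_region <- function(records, density_values, dose_values,
                             covariates, n_resamples = 500L, seed = 1L,
                             alpha = 0.05, time = "time", event = "event") {
  n <- nrow(records)
  stopifnot(length(density_values) == n, length(dose_values) == n)
  if (anyNA(density_values) || anyNA(dose_values)) {
    stop("region values must be complete; drop patients without data first")
  }
  if (sum(records[[event]]) < 1) stop("no events in the data")
  y <- survival::Surv(records[[time]], records[[event]])
  Z <- if (length(covariates)) {
    stats::model.matrix(stats::reformulate(sprintf("`%s`", covariates)),
                        data = records)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), n, 0)
  }
  Xf <- cbind(Z, density = density_values, dose = dose_values,
              inter = density_values * dose_values)
  Xr <- Xf[, -ncol(Xf), drop = FALSE]
  ev <- records[[event]]
  set.seed(seed)
  cvec <- b3 <- pvec <- rep(NA_real_, n_resamples)
  n_redrawn <- 0L
  n_failed <- 0L
  for (r in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(ev[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    ff <- cox_ll_fast(Xf[idx, , drop = FALSE], y[idx])
    fr <- cox_ll_fast(Xr[idx, , drop = FALSE], y[idx])
    if (is.null(ff) || is.null(fr)) {
      n_failed <- n_failed + 1L
      next
    }
    stat <- max(0, 2 * (ff$loglik[2] - fr$loglik[2]))
    pvec[r] <- stats::pchisq(stat, 1, lower.tail = FALSE)
    b3[r] <- ff$coefficients[ncol(Xf)]
    risk <- as.vector(Xf %*% ff$coefficients)
    cvec[r] <- unname(
      survival::concordance(y ~ risk, reverse = TRUE)$concordance)
  }
  if (n_redrawn > 0L) {
    message(sprintf("bootstrap: redrew %d event-free resamples", n_redrawn))
  }
  b3_ci <- stats::quantile(b3, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(n_resamples = as.integer(n_resamples),
         c_index_median = stats::median(cvec, na.rm = TRUE),
         c_index_ci = stats::quantile(cvec, c(0.025, 0.975), na.rm = TRUE,
                                      names = FALSE),
         lr_significant_fraction = 100 * mean(pvec < alpha, na.rm = TRUE),
         b3_ci = b3_ci,
         stable = is.finite(b3_ci[1]) && is.finite(b3_ci[2]) &&
                  sign(b3_ci[1]) == sign(b3_ci[2]) && sign(b3_ci[1]) != 0,
         n_redrawn = n_redrawn, n_failed = n_failed,
         c_index = cvec, b3 = b3, p_value = pvec,
         seed = as.integer(seed)),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "bootstrap_summary: %d resamples; C-index %.3f (%.3f-%.3f); LR sig %.0f%%; b3 CI [%.3f, %.3f] (%s)\n",
    x$n_resamples, x$c_index_median, x$c_index_ci[1], x$c_index_ci[2],
    x$lr_significant_fraction, x$b3_ci[1], x$b3_ci[2],
    if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Evaluate one boxed region as an outcome model
#'
#' Extracts per-patient region means of the density and dose curves,
#' applies the near-zero-variance screen (at the statistic's granularity)
#' and the conditional log transform, fits the full-cohort interaction and
#' no-interaction models, runs the bootstrap stability analysis, and
#' applies the acceptance rule: a region is accepted iff its interaction
#' coefficient is bootstrap-stable AND its median bootstrap C-index
#' exceeds the clinical baseline model's C-index.
#'
#' @param region a boxed `map_region`.
#' @param density_mat,dose_mat curve matrices for the region's statistics.
#' @param records complete-case data frame (`time`, `event`, covariates).
#' @param covariates clinical covariate names.
#' @param baseline_c_index C-index of the clinical baseline model.
#' @param n_resamples,seed,alpha bootstrap settings.
#' @return An object of class `region_model`: the region, extracted
#'   values, transforms, `fit_full`, `fit_reduced`, `bootstrap`,
#'   `status` (`"accepted"`, `"rejected_nzv"`, `"rejected_unstable"`,
#'   `"rejected_c_index"`), and standardised-coefficient report rows.
#' @export
evaluate_region <- function(region, density_mat, dose_mat, records,
                            covariates, baseline_c_index,
                            n_resamples = 500L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(region, "map_region"), region$status == "boxed")
  dens <- extract_region_values(density_mat, region$box$density)
  dose <- extract_region_values(dose_mat, region$box$dose)
  keep <- !is.na(dens) & !is.na(dose)
  recs <- records[keep, , drop = FALSE]
  dens <- dens[keep]
  dose <- dose[keep]
  out <- structure(
    list(region = region, n = sum(keep),
         density_values = dens, dose_values = dose,
         transforms = c(density = FALSE, dose = FALSE),
         fit_full = NULL, fit_reduced = NULL, bootstrap = NULL,
         report = NULL, status = NULL),
    class = "region_model"
  )
  gd <- nzv_granularity(region$metric_pair[1])
  go <- nzv_granularity(region$metric_pair[2])
  if (near_zero_variance(dens, gd) || near_zero_variance(dose, go)) {
    out$status <- "rejected_nzv"
    out$region$status <- "rejected_nzv"
    return(out)
  }
  td <- maybe_log_transform(dens)
  to <- maybe_log_transform(dose)
  dens <- td$values
  dose <- to$values
  out$transforms <- c(density = td$applied, dose = to$applied)
  out$density_values <- dens
  out$dose_values <- dose

  df <- recs
  df$.density <- dens
  df$.dose <- dose
  df$.inter <- dens * dose
  out$fit_full <- fit_cox(df, c(covariates, ".density", ".dose", ".inter"))
  out$fit_reduced <- fit_cox(df, c(covariates, ".density", ".dose"))
  out$lr <- lr_test(out$fit_full, out$fit_reduced)
  out$bootstrap <- bootstrap_region(recs, dens, dose, covariates,
                                    n_resamples = n_resamples, seed = seed,
                                    alpha = alpha)
  # standardised coefficients for reporting only
  dfs <- recs
  dfs$.density <- standardise_for_report(dens)
  dfs$.dose <- standardise_for_report(dose)
  dfs$.inter <- dfs$.density * dfs$.dose
  fs <- fit_cox(dfs, c(covariates, ".density", ".dose", ".inter"))
  fr <- fit_cox(dfs, c(covariates, ".density", ".dose"))
  wald_p <- function(f) {
    z <- f$coefficients / f$se
    2 * stats::pnorm(-abs(z))
  }
  out$report <- list(
    with_interaction = data.frame(
      term = names(fs$coefficients), coef = unname(fs$coefficients),
      p_value = unname(wald_p(fs))),
    without_interaction = data.frame(
      term = names(fr$coefficients), coef = unname(fr$coefficients),
      p_value = unname(wald_p(fr))))
  out$status <- if (!out$bootstrap$stable) {
    "rejected_unstable"
  } else if (!(out$bootstrap$c_index_median > baseline_c_index)) {
    "rejected_c_index"
  } else {
    "accepted"
  }
  out$region$status <- if (out$status == "accepted") "accepted" else out$status
  out
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("region_model (%s x %s): status %s, n = %d\n",
              x$region$metric_pair[1], x$region$metric_pair[2],
              x$status, x$n))
  if (!is.null(x$bootstrap)) print(x$bootstrap)
  invisible(x)
}
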