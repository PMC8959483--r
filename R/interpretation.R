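#' Hazard-ratio contrast curve at a fixed dose level
#'
#' Under the interaction model, the log hazard ratio of density value d
#' relative to the cohort mean density, at dose level D, is
#' `(b2 + b3 * D) * (d - mean density)`. Pointwise 95% CIs come from the
#' delta method on (b2, b3): variance
#' `(d - mean)^2 * (var b2 + D^2 var b3 + 2 D cov(b2, b3))`. Curves for
#' different dose levels all cross zero at the mean density.
#'
#' @param fit a `cox_fit` containing the density, dose and interaction
#'   coefficients.
#' @param density_grid density values to evaluate (x-axis).
#' @param dose_value the dose level D at which to contrast.
#' @param density_mean cohort mean density (reference value).
#' @param density_term,inter_term coefficient names in `fit` (defaults
#'   match [evaluate_region()]).
#' @return An object of class `contrast_curve`: `density_grid`,
#'   `dose_value`, `ln_hr`, `ci_lo`, `ci_hi`.
#' @export
contrast_curve <- function(fit, density_grid, dose_value, density_mean,
                           density_term = ".density", inter_term = ".inter") {
  stopifnot(inherits(fit, "cox_fit"))
  b2 <- fit$coefficients[[density_term]]
  b3 <- fit$coefficients[[inter_term]]
  delta <- density_grid - density_mean
  ln_hr <- (b2 + b3 * dose_value) * delta
  ci_lo <- ci_hi <- rep(NA_real_, length(delta))
  if (!is.null(fit$vcov) && all(c(density_term, inter_term)
                                %in% rownames(fit$vcov))) {
    v <- delta^2 * (fit$vcov[density_term, density_term] +
                    dose_value^2 * fit$vcov[inter_term, inter_term] +
                    2 * dose_value * fit$vcov[density_term, inter_term])
    ci_lo <- ln_hr - 1.96 * sqrt(pmax(v, 0))
    ci_hi <- ln_hr + 1.96 * sqrt(pmax(v, 0))
  } else {
    warning("coefficient covariance unavailable; contrast curve has no CI")
  }
  structure(
    list(density_grid = density_grid, dose_value = dose_value,
         ln_hr = ln_hr, ci_lo = ci_lo, ci_hi = ci_hi),
    class = "contrast_curve"
  )
}

#' Contrast curves at the 10th, 50th and 90th dose percentiles
#'
#' @param model a `region_model` from [evaluate_region()].
#' @param n_grid number of density grid points spanning the observed range.
#' @return Named list of `contrast_curve` objects (`p10`, `median`, `p90`).
#' @export
region_contrast_curves <- function(model, n_grid = 50L) {
  stopifnot(inherits(model, "region_model"), !is.null(model$fit_full))
  dens <- model$density_values
  dose <- model$dose_values
  grid <- seq(min(dens), max(dens), length.out = n_grid)
  levels <- stats::quantile(dose, c(0.1, 0.5, 0.9), names = FALSE)
  out <- lapply(levels, function(D) {
    contrast_curve(model$fit_full, grid, D, mean(dens))
  })
  names(out) <- c("p10", "median", "p90")
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Constant input yields
#' `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3L) stop("need at least 3 complete pairs")
  x <- x[keep]
  y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Confounding report for region metrics
#'
#' Spearman correlations of each region's dose metric against mean GTV
#' dose, motion amplitude and tumour volume, and of each density metric
#' against tumour volume and motion amplitude - the standard sanity matrix
#' for radial dose/density biomarkers.
#'
#' @param density_values named list of per-patient density-metric vectors.
#' @param dose_values named list of per-patient dose-metric vectors.
#' @param volume,motion per-patient tumour volume and motion amplitude.
#' @param mean_gtv_dose per-patient mean dose to the tumour.
#' @return Data frame `(metric, kind, against, rho)`.
#' @export
confounding_report <- function(density_values, dose_values, volume, motion,
                               mean_gtv_dose) {
  rows <- list()
  for (nm in names(dose_values)) {
    for (ag in c("mean_gtv_dose", "motion", "volume")) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = nm, kind = "dose", against = ag,
        rho = spearman(dose_values[[nm]],
                       switch(ag, mean_gtv_dose = mean_gtv_dose,
                              motion = motion, volume = volume)))
    }
  }
  for (nm in names(density_values)) {
    for (ag in c("volume", "motion")) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = nm, kind = "density", against = ag,
        rho = spearman(density_values[[nm]],
                       switch(ag, motion = motion, volume = volume)))
    }
  }
  do.call(rbind, rows)
}

#' Group-wise mean curves with pointwise confidence intervals
#'
#' Pointwise mean over valid patients per annulus for each group, with a
#' normal-approximation 95% CI of the mean. Singleton groups get a mean
#' without a CI.
#'
#' @param mat patients x annuli matrix from [curve_matrix()].
#' @param groups grouping factor/vector, one entry per patient.
#' @return Data frame `(group, distance_cm, n, mean, ci_lo, ci_hi)`.
#' @export
group_mean_curves <- function(mat, groups) {
  stopifnot(nrow(mat) == length(groups))
  d <- attr(mat, "distances")
  out <- lapply(split(seq_len(nrow(mat)), groups), function(idx) {
    sub <- mat[idx, , drop = FALSE]
    n <- colSums(!is.na(sub))
    mu <- suppressWarnings(colMeans(sub, na.rm = TRUE))
    mu[n == 0L] <- NA_real_
    se <- rep(NA_real_, ncol(sub))
    ok <- n >= 2L
    sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
    se[ok] <- sds[ok] / sqrt(n[ok])
    data.frame(distance_cm = d, n = n, mean = mu,
               ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se)
  })
  res <- do.call(rbind, Map(function(g, df) cbind(group = g, df),
                            names(out), out))
  rownames(res) <- NULL
  res
}
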