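#' Dose field container
#'
#' Wraps a non-negative scalar dose volume with its fractionation metadata.
#' `kind` records whether voxel values are total physical dose or EQD2
#' (equivalent dose in 2-Gy fractions).
#'
#' @param values numeric 3D array, Gy, all >= 0.
#' @param grid a [voxel_grid()].
#' @param kind `"physical"` or `"eqd2"`.
#' @param n_fractions positive integer number of treatment fractions.
#' @param alpha_beta tissue alpha/beta ratio in Gy (10 for tumour effect).
#' @return An object of class `dose_field`.
#' @export
dose_field <- function(values, grid, kind = c("physical", "eqd2"),
                       n_fractions = 5L, alpha_beta = 10) {
  kind <- match.arg(kind)
  check_volume(values, grid, "dose")
  if (any(values < 0, na.rm = TRUE)) stop("dose values must be >= 0")
  if (length(n_fractions) != 1L || n_fractions <= 0) {
    stop("n_fractions must be a positive integer")
  }
  if (alpha_beta <= 0) stop("alpha_beta must be positive (Gy)")
  structure(
    list(values = values, grid = grid, kind = kind,
         n_fractions = as.integer(n_fractions), alpha_beta = alpha_beta),
    class = "dose_field"
  )
}

#' Respiratory motion model
#'
#' Per-phase rigid translation vectors (mm) relative to the reference
#' phase, with non-negative phase weights normalised to sum to one. The
#' reference phase must have translation (0, 0, 0).
#'
#' @param translations numeric matrix, phases x 3, mm.
#' @param weights optional per-phase weights; default uniform.
#' @param reference integer index of the reference phase.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(translations, weights = NULL, reference = 1L) {
  translations <- as.matrix(translations)
  stopifnot(ncol(translations) == 3L, nrow(translations) >= 1L)
  if (any(abs(translations[reference, ]) > 1e-9)) {
    stop("reference phase translation must be (0,0,0)")
  }
  n <- nrow(translations)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n || any(weights < 0)) {
    stop("weights must be non-negative, one per phase")
  }
  weights <- weights / sum(weights)
  structure(
    list(translations = translations, weights = weights,
         reference = as.integer(reference)),
    class = "motion_model"
  )
}

# Trilinear resampling of `vol` at every voxel centre shifted by a constant
# physical translation t_mm; samples outside the grid clamp to the nearest
# in-grid voxel (replicate padding).
trilinear_shift <- function(vol, grid, t_mm) {
  d <- grid$dims
  off <- t_mm / grid$spacing
  i0 <- floor(off)
  fr <- off - i0
  ax_idx <- function(axis, plus) {
    pmin(pmax(seq_len(d[axis]) + i0[axis] + plus, 1L), d[axis])
  }
  out <- array(0, d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) fr[1] else 1 - fr[1]) *
         (if (cy) fr[2] else 1 - fr[2]) *
         (if (cz) fr[3] else 1 - fr[3])
    if (w == 0) next
    out <- out + w * vol[ax_idx(1, cx), ax_idx(2, cy), ax_idx(3, cz)]
  }
  out
}

#' Blur a dose field for respiratory motion
#'
#' Shift-and-add estimate of the dose delivered to moving tissue: the
#' output at voxel x is the phase-weighted mean of the planned dose sampled
#' (trilinearly) at x + t_p over all phase translations t_p. Must be
#' applied to physical dose, before EQD2 conversion.
#'
#' @param dose a `dose_field` with `kind = "physical"`.
#' @param motion a [motion_model()].
#' @return A blurred `dose_field`, still physical dose.
#' @export
blur_dose_for_motion <- function(dose, motion) {
  stopifnot(inherits(dose, "dose_field"), inherits(motion, "motion_model"))
  if (dose$kind != "physical") stop("motion blur must precede EQD2 conversion")
  acc <- array(0, dose$grid$dims)
  for (p in seq_len(nrow(motion$translations))) {
    w <- motion$weights[p]
    if (w == 0) next
    acc <- acc + w * trilinear_shift(dose$values, dose$grid,
                                     motion$translations[p, ])
  }
  dose$values <- acc
  dose
}

#' Convert physical dose to EQD2
#'
#' Linear-quadratic iso-effect conversion: with per-fraction dose
#' d = D / n, `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)`. The
#' conversion is the identity exactly at 2 Gy per fraction.
#'
#' @param dose a `dose_field` with `kind = "physical"`.
#' @return A `dose_field` with `kind = "eqd2"`.
#' @export
to_eqd2 <- function(dose) {
  stopifnot(inherits(dose, "dose_field"))
  if (dose$kind != "physical") stop("dose is already EQD2")
  if (dose$n_fractions <= 0) stop("n_fractions must be positive")
  d <- dose$values / dose$n_fractions
  dose$values <- dose$values * (d + dose$alpha_beta) / (2 + dose$alpha_beta)
  dose$kind <- "eqd2"
  dose
}

#' Generalised (power) mean of a dose distribution
#'
#' `(sum_i v_i D_i^a)^(1/a)` with weights `v_i` normalised to sum to one.
#' `a = 1` is the arithmetic mean, `a = -1` the harmonic mean; the mean
#' tends to the minimum dose as a -> -Inf and the maximum as a -> +Inf.
#' Negative exponents emphasise cold spots, which is why they are used to
#' summarise dose to possible microscopic disease.
#'
#' @param d dose values, Gy (e.g. histogram bin centres).
#' @param v non-negative weights (e.g. an annulus mass column); need not be
#'   normalised.
#' @param a non-zero exponent.
#' @return The generalised mean in Gy, or `NA` if total weight is zero.
#' @export
generalised_mean <- function(d, v, a) {
  stopifnot(length(d) == length(v))
  if (length(a) != 1L || a == 0) stop("exponent a must be a single non-zero value")
  tot <- sum(v)
  if (tot <= 0) return(NA_real_)
  keep <- v > 0
  d <- d[keep]
  v <- v[keep] / tot
  if (a < 0 && any(d <= 0)) {
    stop("generalised mean undefined for non-positive dose with a < 0")
  }
  if (any(d == 0)) return(0)                       # a > 0, zero dose present
  # log-sum-exp for numerical stability at large |a|
  lx <- a * log(d)
  m <- max(lx)
  exp((m + log(sum(v * exp(lx - m)))) / a)
}

#' Mass-weighted standard deviation
#'
#' Population-style weighted SD, `sqrt(sum v (x - mu)^2)` with normalised
#' weights; used per annulus on histogram bin centres.
#'
#' @param x values (bin centres).
#' @param v non-negative weights.
#' @return Weighted SD, or `NA` if total weight is zero.
#' @export
weighted_sd <- function(x, v) {
  tot <- sum(v)
  if (tot <= 0) return(NA_real_)
  v <- v / tot
  mu <- sum(v * x)
  sqrt(sum(v * (x - mu)^2))
}

#' Fraction of mass below a dose threshold
#'
#' The mass fraction in bins whose centre is below `threshold` (default
#' 30 Gy EQD2, a conventional cut for inadequate treatment of microscopic
#' disease).
#'
#' @param d bin centres, Gy.
#' @param v non-negative weights.
#' @param threshold Gy.
#' @return Fraction in `[0, 1]`, or `NA` if total weight is zero.
#' @export
fraction_below <- function(d, v, threshold = 30) {
  tot <- sum(v)
  if (tot <= 0) return(NA_real_)
  sum(v[d < threshold]) / tot
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' @param x numeric vector.
#' @return Skewness, `NA` if fewer than 3 finite values or zero variance.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Exponent-selection diagnostic for the generalised mean
#'
#' For each candidate exponent, computes the cohort's generalised-mean dose
#' per patient and its sample skewness. The recommended exponent is the
#' most negative candidate whose cohort skewness magnitude stays within
#' `skew_bound`; more negative exponents buy little change in the average
#' while inflating skew.
#'
#' @param cohort_doses list with one element per patient, each a list or
#'   data frame with components `d` (dose values) and `v` (weights), e.g.
#'   one annulus column of the dose radial histogram.
#' @param a_candidates integer exponents to test (default -1 to -5).
#' @param skew_bound maximum acceptable |skewness| (default 3).
#' @return A data frame `(a, skewness)` with attribute `recommended_a`.
#' @export
exponent_diagnostic <- function(cohort_doses, a_candidates = -1:-5,
                                skew_bound = 3) {
  if (length(cohort_doses) < 3L) stop("need at least 3 patients")
  gm <- vapply(a_candidates, function(a) {
    vals <- vapply(cohort_doses, function(p) generalised_mean(p$d, p$v, a),
                   numeric(1))
    sample_skewness(vals)
  }, numeric(1))
  out <- data.frame(a = a_candidates, skewness = gm)
  # scan outward in |a|; stop before the first exceedance of the bound
  rec <- NA_integer_
  for (i in order(abs(a_candidates))) {
    if (!is.na(gm[i]) && abs(gm[i]) <= skew_bound) rec <- a_candidates[i] else break
  }
  attr(out, "recommended_a") <- rec
  out
}
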