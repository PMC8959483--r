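#' Covariate availability filter and complete-case reduction
#'
#' Drops candidate covariates available for fewer than
#' `availability_threshold` of patients, then removes rows with any
#' missing value in the kept covariates (complete-case analysis).
#'
#' @param records data frame with survival columns and covariates.
#' @param covariates character vector of candidate covariate names.
#' @param availability_threshold minimum non-missing fraction (default 0.9).
#' @return List with `kept` (covariate names) and `records` (complete-case
#'   data frame).
#' @export
filter_covariates <- function(records, covariates,
                              availability_threshold = 0.90) {
  stopifnot(all(covariates %in% names(records)))
  avail <- vapply(records[covariates],
                  function(x) mean(!is.na(x)), numeric(1))
  kept <- covariates[avail >= availability_threshold]
  if (length(kept)) {
    cc <- stats::complete.cases(records[kept])
    records <- records[cc, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no patients remain after complete-case filtering")
  list(kept = kept, records = records)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial-likelihood fit with Efron handling of tied event times,
#' plus Harrell's concordance on the fitted risk scores. An empty term list
#' fits the null model (C-index 0.5 by convention). A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param records data frame containing `time`, `event` and the covariates.
#' @param terms character vector of covariate column names (may be empty).
#' @param time,event names of the survival columns.
#' @param ties tie-handling method passed to [survival::coxph()]
#'   (`"efron"` default; `"breslow"` makes the partial likelihood exactly
#'   invariant to record duplication).
#' @return An object of class `cox_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik` (at the fitted coefficients), `loglik_null`, `c_index`, `n`,
#'   `n_events`, `terms`.
#' @export
fit_cox <- function(records, terms = character(), time = "time",
                    event = "event", ties = "efron") {
  stopifnot(time %in% names(records), event %in% names(records))
  if (any(records[[time]] <= 0)) stop("survival times must be > 0")
  if (sum(records[[event]]) < 1) stop("no events in the data")
  y <- survival::Surv(records[[time]], records[[event]])
  if (length(terms) == 0L) {
    ll <- survival::coxph(y ~ 1)$loglik[1]
    return(structure(
      list(coefficients = numeric(0), se = numeric(0),
           vcov = matrix(0, 0, 0), loglik = ll, loglik_null = ll,
           c_index = 0.5, n = nrow(records),
           n_events = sum(records[[event]]), terms = character()),
      class = "cox_fit"
    ))
  }
  stopifnot(all(terms %in% names(records)))
  X <- stats::model.matrix(
    stats::reformulate(sprintf("`%s`", terms)), data = records)[, -1, drop = FALSE]
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    drop_idx <- qx$pivot[seq(qx$rank + 1L, ncol(X) + 1L)]
    bad <- colnames(X)[drop_idx[drop_idx > 1L] - 1L]
    stop(sprintf("singular design: collinear terms {%s}",
                 paste(bad, collapse = ", ")))
  }
  df <- records
  df$.y <- y
  fml <- stats::reformulate(sprintf("`%s`", terms), response = ".y")
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("singular design: collinear terms {%s}",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(coefficients = stats::coef(fit),
         se = sqrt(diag(stats::vcov(fit))),
         vcov = stats::vcov(fit),
         loglik = fit$loglik[2],
         loglik_null = fit$loglik[1],
         c_index = unname(fit$concordance["concordance"]),
         n = fit$n, n_events = fit$nevent, terms = terms),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d, C-index = %.3f, loglik = %.3f\n",
              x$n, x$n_events, x$c_index, x$loglik))
  if (length(x$coefficients)) {
    print(data.frame(coef = x$coefficients, se = x$se,
                     z = x$coefficients / x$se))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' Twice the log partial-likelihood difference referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in number
#' of coefficients (1 when testing a single interaction term).
#'
#' @param full,reduced `cox_fit` objects, `reduced` nested in `full`.
#' @return A list of class `lr_test`: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 1L) stop("full model must have more coefficients than reduced")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6 * max(1, abs(full$loglik))) {
    stop("non-nested or non-converged: full log-likelihood below reduced")
  }
  stat <- max(stat, 0)
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
    class = "lr_test"
  )
}

# Fast partial-likelihood fit on a prebuilt design matrix (no formula
# machinery); returns NULL on failure, non-convergence, or runaway
# coefficients (separation) instead of raising.
cox_ll_fast <- function(X, y) {
  ctrl <- survival::coxph.control(iter.max = 25)
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      x = X, y = y, strata = NULL, offset = NULL, init = NULL,
      control = ctrl, weights = NULL,
      method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients) ||
      any(!is.finite(fit$coefficients)) ||
      (!is.null(fit$iter) && fit$iter >= 25) ||
      any(abs(fit$coefficients) > 50)) {
    return(NULL)
  }
  fit
}

#' Map of interaction significance over all radial location pairs
#'
#' For every pair (density annulus i, dose annulus j), patients with valid
#' values at both annuli enter two Cox models sharing the clinical
#' covariates: one with density_i, dose_j and their product, one without
#' the product. The likelihood-ratio p-value of the interaction term fills
#' cell (i, j). Cells with fewer than `min_events` events among eligible
#' patients, or with a degenerate fit, are left missing (with a warning
#' summary), never an error.
#'
#' @param density_mat patients x density-annuli matrix from
#'   [curve_matrix()] (NA = invalid annulus).
#' @param dose_mat patients x dose-annuli matrix, same patient order.
#' @param records complete-case data frame with `time`, `event` and the
#'   clinical covariates; same patient order as the matrices.
#' @param covariates character vector of clinical covariate names.
#' @param metric_pair character length 2, (density statistic, dose
#'   statistic), recorded on the map.
#' @param min_events minimum events required to attempt a cell fit.
#' @param time,event survival column names.
#' @return An object of class `interaction_map`: `p_values` and `n_used`
#'   (density x dose matrices), `metric_pair`, `density_distances`,
#'   `dose_distances`, `min_events`.
#' @export
interaction_map <- function(density_mat, dose_mat, records, covariates,
                            metric_pair = c("density", "dose"),
                            min_events = 10L, time = "time", event = "event") {
  stopifnot(nrow(density_mat) == nrow(records),
            nrow(dose_mat) == nrow(records))
  y_all <- survival::Surv(records[[time]], records[[event]])
  Z <- if (length(covariates)) {
    stats::model.matrix(stats::reformulate(sprintf("`%s`", covariates)),
                        data = records)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow(records), 0)
  }
  ni <- ncol(density_mat)
  nj <- ncol(dose_mat)
  p <- matrix(NA_real_, ni, nj)
  n_used <- matrix(NA_integer_, ni, nj)
  ev <- records[[event]]
  n_failed <- 0L
  for (i in seq_len(ni)) {
    x1_all <- density_mat[, i]
    for (j in seq_len(nj)) {
      x2_all <- dose_mat[, j]
      keep <- !is.na(x1_all) & !is.na(x2_all)
      n_used[i, j] <- sum(keep)
      if (sum(ev[keep]) < min_events) next
      x1 <- x1_all[keep]
      x2 <- x2_all[keep]
      if (stats::sd(x1) == 0 || stats::sd(x2) == 0) next
      Xr <- cbind(Z[keep, , drop = FALSE], density = x1, dose = x2)
      Xf <- cbind(Xr, inter = x1 * x2)
      yk <- y_all[keep]
      ff <- cox_ll_fast(Xf, yk)
      fr <- cox_ll_fast(Xr, yk)
      if (is.null(ff) || is.null(fr)) {
        n_failed <- n_failed + 1L
        next
      }
      stat <- max(0, 2 * (ff$loglik[2] - fr$loglik[2]))
      p[i, j] <- stats::pchisq(stat, 1, lower.tail = FALSE)
    }
  }
  if (n_failed > 0L) {
    warning(sprintf("%d map cells left missing after fit failures", n_failed))
  }
  structure(
    list(p_values = p, n_used = n_used, metric_pair = metric_pair,
         density_distances = attr(density_mat, "distances"),
         dose_distances = attr(dose_mat, "distances"),
         min_events = as.integer(min_events)),
    class = "interaction_map"
  )
}

#' Density and dose statistics used for the nine standard maps
#' @return Character vectors of statistic names.
#' @export
density_statistics <- function() c("mean", "sd", "p90")

#' @rdname density_statistics
#' @export
dose_statistics <- function() c("dose_sd", "gen_mean", "fraction_below")

#' All interaction maps for the standard metric combinations
#'
#' One map per (density statistic, dose statistic) pair - nine in total
#' with the default statistic sets.
#'
#' @param density_curves named list of patients x annuli matrices, one per
#'   density statistic.
#' @param dose_curves named list of patients x annuli matrices, one per
#'   dose statistic.
#' @inheritParams interaction_map
#' @return Named list of `interaction_map` objects
#'   (`"<density>.x.<dose>"`).
#' @export
interaction_maps <- function(density_curves, dose_curves, records,
                             covariates, min_events = 10L) {
  maps <- list()
  for (ds in names(density_curves)) {
    for (os in names(dose_curves)) {
      maps[[paste(ds, os, sep = ".x.")]] <- interaction_map(
        density_curves[[ds]], dose_curves[[os]], records, covariates,
        metric_pair = c(ds, os), min_events = min_events)
    }
  }
  maps
}

#' Write an interaction map as CSV plus a JSON sidecar
#'
#' The CSV holds the p-value matrix with distance headers; the sidecar
#' records the metric pair, per-cell patient counts and settings.
#'
#' @param map an `interaction_map`.
#' @param path CSV output path (sidecar gets extension `.json`).
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  m <- as.data.frame(map$p_values)
  names(m) <- sprintf("dose_%g_cm", map$dose_distances)
  m <- cbind(density_cm = map$density_distances, m)
  utils::write.csv(m, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(metric_pair = map$metric_pair,
         min_events = map$min_events,
         n_used = map$n_used,
         density_distances = map$density_distances,
         dose_distances = map$dose_distances),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
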