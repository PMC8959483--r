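# Independent oracles used by the unit and acceptance tests. These are
# written with plain loops / direct formulas, deliberately not sharing code
# with the package implementation.

# Exhaustive signed distance: border found by explicit 6-neighbour loops,
# distance by all-pairs minimisation over border voxels.
brute_signed_distance <- function(mask, spacing) {
  d <- dim(mask)
  is_border <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nbs <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                 c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (r in seq_len(6)) {
      p <- nbs[r, ]
      outside <- any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3]
      if (outside || !mask[p[1], p[2], p[3]]) {
        is_border[i, j, k] <- TRUE
        break
      }
    }
  }
  bd <- which(is_border, arr.ind = TRUE)
  bp <- sweep(bd, 2, spacing, "*")
  ix <- which(array(TRUE, d), arr.ind = TRUE)
  pp <- sweep(ix, 2, spacing, "*")
  d2 <- outer(pp[, 1], bp[, 1], "-")^2 +
        outer(pp[, 2], bp[, 2], "-")^2 +
        outer(pp[, 3], bp[, 3], "-")^2
  out <- array(sqrt(apply(d2, 1, min)), d)
  out[mask & !is_border] <- -out[mask & !is_border]
  out
}

# a random non-empty, non-full blob: union of 1-3 random ellipsoids
random_mask <- function(dims, n_blobs = sample(1:3, 1)) {
  d <- dims
  m <- array(FALSE, d)
  for (b in seq_len(n_blobs)) {
    c0 <- runif(3, 0.3, 0.7) * d
    ax <- runif(3, 1.2, 0.3 * max(d))
    q <- outer(outer(((seq_len(d[1]) - c0[1]) / ax[1])^2,
                     ((seq_len(d[2]) - c0[2]) / ax[2])^2, "+"),
               ((seq_len(d[3]) - c0[3]) / ax[3])^2, "+")
    m <- m | (q <= 1)
  }
  if (!any(m)) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  m[1, 1, 1] <- FALSE
  m
}

# Direct SSIM evaluation: Gaussian-weighted local moments computed per
# interior pixel with explicit loops over the 11x11 window.
direct_ssim <- function(a, b, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  lo <- min(a, b)
  hi <- max(a, b)
  if (hi <= lo) return(1)
  x <- (a - lo) / (hi - lo)
  y <- (b - lo) / (hi - lo)
  h <- (win - 1L) %/% 2L
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- outer(g, g) / sum(outer(g, g))
  C1 <- K1^2
  C2 <- K2^2
  d <- dim(x)
  vals <- c()
  for (i in (h + 1):(d[1] - h)) for (j in (h + 1):(d[2] - h)) {
    px <- x[(i - h):(i + h), (j - h):(j + h)]
    py <- y[(i - h):(i + h), (j - h):(j + h)]
    mx <- sum(w * px)
    my <- sum(w * py)
    vx <- sum(w * px^2) - mx^2
    vy <- sum(w * py^2) - my^2
    cxy <- sum(w * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                     ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# Cox partial log-likelihood for a single covariate, no ties (direct form)
cox_partial_ll <- function(b, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

# two-stage 1-D grid maximisation of the partial likelihood
grid_search_cox <- function(time, event, x, lo = -4, hi = 4) {
  g1 <- seq(lo, hi, by = 1e-3)
  v1 <- vapply(g1, cox_partial_ll, numeric(1), time = time, event = event, x = x)
  b0 <- g1[which.max(v1)]
  g2 <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  v2 <- vapply(g2, cox_partial_ll, numeric(1), time = time, event = event, x = x)
  g2[which.max(v2)]
}

# fabricate an annulus_labels object with hand-assigned labels
make_labels <- function(labels_array, window, grid) {
  n <- as.integer(round(10 * (window[2] - window[1])))
  structure(
    list(labels = labels_array, window = window, n_annuli = n,
         centres_cm = (window[1] * 10 + seq_len(n) - 0.5) / 10,
         grid = grid),
    class = "annulus_labels")
}

# fabricate a summary_curve
make_curve <- function(values, valid = rep(TRUE, length(values)),
                       distances = seq_along(values) / 10,
                       statistic = "mean", patient_id = "T") {
  structure(list(statistic = statistic, distances = distances,
                 values = values, valid = valid, patient_id = patient_id),
            class = "summary_curve")
}
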