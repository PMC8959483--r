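# Zero-padded "same" correlation of a matrix with a symmetric 1D kernel
# along rows (along = 1) or columns (along = 2).
conv1d_same <- function(m, w, along) {
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  h <- (length(w) - 1L) %/% 2L
  for (s in -h:h) {
    wt <- w[s + h + 1L]
    if (along == 1L) {
      src <- seq_len(d[1]) + s
      ok <- src >= 1L & src <= d[1]
      if (any(ok)) out[ok, ] <- out[ok, ] + wt * m[src[ok], , drop = FALSE]
    } else {
      src <- seq_len(d[2]) + s
      ok <- src >= 1L & src <= d[2]
      if (any(ok)) out[, ok] <- out[, ok] + wt * m[, src[ok], drop = FALSE]
    }
  }
  out
}

gaussian_taps <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1L) %/% 2L
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

as_hist_matrix <- function(x) {
  if (inherits(x, "radial_histogram")) x$mass else as.matrix(x)
}

#' Mean structural similarity of two radial histograms
#'
#' Canonical SSIM (11-tap Gaussian window with sigma 1.5, K1 = 0.01,
#' K2 = 0.03) evaluated on the two mass tables after joint min-max
#' normalisation, so the data range is well defined and equal to 1. Local
#' statistics use the Gaussian-weighted (not sample-corrected) moments, and
#' the mean is taken over the interior region unaffected by edge padding.
#' Identical inputs give exactly 1.
#'
#' @param a,b `radial_histogram` objects (or plain matrices) of one shape.
#' @param win_size odd window size (default 11).
#' @param sigma Gaussian window standard deviation in bins (default 1.5).
#' @param K1,K2 the usual SSIM stabilisation constants.
#' @return Scalar mean SSIM.
#' @export
ssim <- function(a, b, win_size = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  x <- as_hist_matrix(a)
  y <- as_hist_matrix(b)
  if (!identical(dim(x), dim(y))) stop("histograms have different shapes")
  if (inherits(a, "radial_histogram") && inherits(b, "radial_histogram") &&
      !isTRUE(all.equal(a$value_bin_edges, b$value_bin_edges))) {
    stop("histograms have different value bin edges")
  }
  h <- (win_size - 1L) %/% 2L
  if (any(dim(x) < win_size)) {
    stop(sprintf("histogram dims must be >= the %d-point SSIM window", win_size))
  }
  lo <- min(x, y)
  hi <- max(x, y)
  if (hi <= lo) return(1)                    # jointly constant tables
  x <- (x - lo) / (hi - lo)
  y <- (y - lo) / (hi - lo)
  L <- 1
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  w <- gaussian_taps(win_size, sigma)
  smooth2 <- function(m) conv1d_same(conv1d_same(m, w, 1L), w, 2L)
  mx <- smooth2(x)
  my <- smooth2(y)
  exx <- smooth2(x * x)
  eyy <- smooth2(y * y)
  exy <- smooth2(x * y)
  vx <- exx - mx^2
  vy <- eyy - my^2
  cxy <- exy - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  d <- dim(s)
  mean(s[(h + 1L):(d[1] - h), (h + 1L):(d[2] - h)])
}

#' Score every respiratory phase by neighbour similarity
#'
#' For each phase the total score is the SSIM to the previous phase plus
#' the SSIM to the next phase; the respiratory cycle is treated as
#' periodic, so the first and last phases are neighbours.
#'
#' @param histograms list of per-phase `radial_histogram` objects (cropped
#'   to the density window), length >= 3.
#' @return A data frame with one row per phase: `phase`, `ssim_prev`,
#'   `ssim_next`, `ssim_total`, `selected`.
#' @export
phase_scores <- function(histograms) {
  n <- length(histograms)
  if (n < 3L) stop("phase selection needs at least 3 phases")
  # SSIM between consecutive phases (cyclic): pair[i] = ssim(i, i+1 mod n)
  pair <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    ssim(histograms[[i]], histograms[[j]])
  }, numeric(1))
  prev_pair <- pair[c(n, seq_len(n - 1L))]     # ssim(i-1, i)
  total <- prev_pair + pair
  best <- which.max(total)                     # ties -> lowest index
  data.frame(phase = seq_len(n),
             ssim_prev = prev_pair,
             ssim_next = pair,
             ssim_total = total,
             selected = seq_len(n) == best)
}

#' Select the optimal respiratory phase
#'
#' Returns the phase maximising the summed SSIM to its cyclic neighbours;
#' ties are broken towards the lowest phase index.
#'
#' @inheritParams phase_scores
#' @return A list of class `phase_score`: `phase_index` (1-based),
#'   `ssim_prev`, `ssim_next`, `ssim_total`, and the full `scores` table.
#' @export
select_optimal_phase <- function(histograms) {
  sc <- phase_scores(histograms)
  i <- which(sc$selected)
  structure(
    list(phase_index = i,
         ssim_prev = sc$ssim_prev[i],
         ssim_next = sc$ssim_next[i],
         ssim_total = sc$ssim_total[i],
         scores = sc),
    class = "phase_score"
  )
}
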