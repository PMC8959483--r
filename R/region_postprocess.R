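#' Binary significance grid from an interaction map
#'
#' A cell is significant iff its p-value is present and below `alpha`;
#' missing cells are never significant.
#'
#' @param map an `interaction_map`.
#' @param alpha significance level (default 0.05).
#' @return Logical density x dose matrix.
#' @export
significant_cells <- function(map, alpha = 0.05) {
  stopifnot(inherits(map, "interaction_map"))
  out <- !is.na(map$p_values) & map$p_values < alpha
  out
}

new_map_region <- function(cells, map, status = "raw") {
  structure(
    list(cells = cells,                      # logical density x dose matrix
         density_distances = map$density_distances,
         dose_distances = map$dose_distances,
         metric_pair = map$metric_pair,
         box = NULL,
         status = status),
    class = "map_region"
  )
}

#' Connected components of a significance grid
#'
#' 8-connected components in map-index space: diagonal neighbours belong
#' to one region.
#'
#' @param binary logical matrix (from [significant_cells()]).
#' @param map the `interaction_map` the grid came from (for distances).
#' @return List of `map_region` objects with status `"raw"`.
#' @export
connected_regions <- function(binary, map) {
  d <- dim(binary)
  lab <- matrix(0L, d[1], d[2])
  nxt <- 0L
  idx <- which(binary)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i <- ((cur - 1L) %% d[1]) + 1L
      j <- ((cur - 1L) %/% d[1]) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di
        jj <- j + dj
        if (ii < 1L || ii > d[1] || jj < 1L || jj > d[2]) next
        if (binary[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue <- c(queue, (jj - 1L) * d[1] + ii)
        }
      }
    }
  }
  lapply(seq_len(nxt), function(k) new_map_region(lab == k, map))
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Remove thin rows and columns from a map region
#'
#' Iteratively deletes every density row (and dose column) of the region
#' whose longest contiguous run of region cells is shorter than
#' `min_thickness` cells (cells are 1 mm in both axes), repeating until
#' stable. The region may come out empty.
#'
#' @param region a `map_region`.
#' @param min_thickness minimum run length in cells (default 3 = 3 mm).
#' @return The pruned `map_region` (status `"pruned"`).
#' @export
prune_thin <- function(region, min_thickness = 3L) {
  cells <- region$cells
  repeat {
    before <- cells
    for (i in seq_len(nrow(cells))) {
      if (any(cells[i, ]) && max_run(cells[i, ]) < min_thickness) {
        cells[i, ] <- FALSE
      }
    }
    for (j in seq_len(ncol(cells))) {
      if (any(cells[, j]) && max_run(cells[, j]) < min_thickness) {
        cells[, j] <- FALSE
      }
    }
    if (identical(cells, before)) break
  }
  region$cells <- cells
  region$status <- "pruned"
  region
}

#' Box a pruned region and screen on minimum size
#'
#' The region is replaced by a rectangle centred on its cell centroid.
#' The density-axis extent is the mean, over occupied dose columns, of the
#' region's row span in that column (and symmetrically for the dose axis).
#' If either mean extent falls below `min_box_mm` the region is rejected.
#' Box intervals are clipped to the map windows.
#'
#' @param region a pruned `map_region`.
#' @param min_box_mm minimum box height/width in mm (default 3).
#' @return The `map_region` with `box` set (intervals in cm:
#'   `density`, `dose`, plus `width_mm`, `height_mm`) and status
#'   `"boxed"` or `"rejected_size"`.
#' @export
box_and_screen <- function(region, min_box_mm = 3) {
  cells <- region$cells
  if (!any(cells)) {
    region$status <- "rejected_size"
    return(region)
  }
  ij <- which(cells, arr.ind = TRUE)
  dens_c <- region$density_distances   # cm, one per row
  dose_c <- region$dose_distances      # cm, one per column
  centre <- c(mean(dens_c[ij[, 1]]), mean(dose_c[ij[, 2]]))
  # mean row-span across occupied columns = density (width) extent, mm
  occ_j <- sort(unique(ij[, 2]))
  width_mm <- mean(vapply(occ_j, function(j) {
    r <- range(which(cells[, j]))
    diff(r) + 1
  }, numeric(1)))
  occ_i <- sort(unique(ij[, 1]))
  height_mm <- mean(vapply(occ_i, function(i) {
    r <- range(which(cells[i, ]))
    diff(r) + 1
  }, numeric(1)))
  win_d <- c(dens_c[1] - 0.05, dens_c[length(dens_c)] + 0.05)
  win_o <- c(dose_c[1] - 0.05, dose_c[length(dose_c)] + 0.05)
  box_d <- centre[1] + c(-1, 1) * width_mm / 20   # mm -> cm half-extent
  box_o <- centre[2] + c(-1, 1) * height_mm / 20
  region$box <- list(
    density = c(max(box_d[1], win_d[1]), min(box_d[2], win_d[2])),
    dose = c(max(box_o[1], win_o[1]), min(box_o[2], win_o[2])),
    centre = centre, width_mm = width_mm, height_mm = height_mm)
  region$status <- if (width_mm < min_box_mm || height_mm < min_box_mm) {
    "rejected_size"
  } else {
    "boxed"
  }
  region
}

#' Near-zero-variance screen for extracted region values
#'
#' Values are rounded to the domain granularity (0.1 Gy, 1 HU, or 1
#' percentage point). The flag is TRUE - the variable is degenerate - iff
#' fewer than `unique_cut` of the values are unique AND the most common
#' value is more than `freq_ratio_cut` times as frequent as the second
#' most common (the caret defaults, 10% and 95/5 = 19). An all-identical
#' vector is degenerate (infinite frequency ratio).
#'
#' @param values per-patient numeric vector (>= 2 values).
#' @param granularity rounding step in the value's units.
#' @param unique_cut maximum unique fraction (default 0.10).
#' @param freq_ratio_cut frequency-ratio threshold (default 19).
#' @return Logical flag.
#' @export
near_zero_variance <- function(values, granularity, unique_cut = 0.10,
                               freq_ratio_cut = 19) {
  stopifnot(length(values) >= 2L, granularity > 0)
  r <- round(values / granularity)
  tab <- sort(table(r), decreasing = TRUE)
  if (length(tab) == 1L) return(TRUE)
  unique_frac <- length(tab) / length(values)
  ratio <- as.numeric(tab[1]) / as.numeric(tab[2])
  (unique_frac < unique_cut) && (ratio > freq_ratio_cut)
}

#' Rounding granularity for the near-zero-variance screen
#'
#' 0.1 Gy for dose statistics, 1 percentage point for volume fractions,
#' 1 HU for density statistics.
#'
#' @param statistic a statistic name as used in [annulus_stats()].
#' @return Numeric granularity.
#' @export
nzv_granularity <- function(statistic) {
  switch(statistic,
         dose_sd = , gen_mean = 0.1,
         fraction_below = 0.01,
         mean = , sd = , p90 = 1,
         stop(sprintf("unknown statistic '%s'", statistic)))
}

#' Full post-processing of one interaction map
#'
#' Significant cells -> 8-connected components -> thin-row/column pruning
#' -> box averaging with the minimum-size screen. (The near-zero-variance
#' screen needs per-patient extracted values and is applied during region
#' evaluation.)
#'
#' @param map an `interaction_map`.
#' @param alpha significance level.
#' @param min_thickness,min_box_mm pruning and box thresholds (3 mm).
#' @return List of `map_region` objects, boxed or rejected.
#' @export
postprocess_map <- function(map, alpha = 0.05, min_thickness = 3L,
                            min_box_mm = 3) {
  sig <- significant_cells(map, alpha)
  regions <- connected_regions(sig, map)
  lapply(regions, function(r) box_and_screen(prune_thin(r, min_thickness),
                                             min_box_mm))
}

#' @export
print.map_region <- function(x, ...) {
  cat(sprintf("map_region [%s x %s]: %d cells, status %s\n",
              x$metric_pair[1], x$metric_pair[2], sum(x$cells), x$status))
  if (!is.null(x$box)) {
    cat(sprintf("  box: density [%.2f, %.2f] cm, dose [%.2f, %.2f] cm\n",
                x$box$density[1], x$box$density[2],
                x$box$dose[1], x$box$dose[2]))
  }
  invisible(x)
}
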