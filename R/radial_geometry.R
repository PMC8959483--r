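#' Voxel grid descriptor
#'
#' A light-weight description of a regular, possibly anisotropic, voxel
#' grid: integer dimensions and the physical spacing (mm) along each axis.
#' All volumetric inputs in this package (images, masks, dose fields) are
#' plain 3D arrays carried alongside a `voxel_grid`.
#'
#' @param dims integer vector of length 3, number of voxels along x, y, z.
#' @param spacing numeric vector of length 3, mm per voxel along each axis.
#' @return An object of class `voxel_grid` with elements `dims`, `spacing`
#'   and `voxel_volume` (mm^3).
#' @export
voxel_grid <- function(dims, spacing) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  stopifnot(length(dims) == 3L, length(spacing) == 3L)
  if (any(dims < 1L)) stop("grid dims must be >= 1 on every axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid spacing must be positive on every axis")
  }
  structure(
    list(dims = dims, spacing = spacing, voxel_volume = prod(spacing)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels at %g x %g x %g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

check_volume <- function(vol, grid, what = "volume") {
  if (!identical(dim(vol), grid$dims)) {
    stop(sprintf("%s dimensions do not match the grid", what))
  }
  invisible(TRUE)
}

# Logical array shifted by one voxel along `axis` in direction `dir`;
# out-of-grid neighbours are FALSE (treated as background).
shift_mask <- function(mask, axis, dir) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  n <- d[axis]
  if (n == 1L) return(out)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1L)
  } else {
    idx_dst[[axis]] <- 1:(n - 1L)
    idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Border voxels of a binary mask
#'
#' A mask voxel belongs to the border if at least one of its six
#' face-adjacent neighbours is background. Neighbours outside the grid
#' count as background, so mask voxels on the grid boundary are border.
#'
#' @param mask logical 3D array.
#' @return Logical 3D array marking border voxels.
#' @export
mask_border <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- mask & TRUE  # coerce to logical, keep dims
  all_nb <- array(TRUE, dim(mask))
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      all_nb <- all_nb & shift_mask(mask, axis, dir)
    }
  }
  mask & !all_nb
}

#' Signed Euclidean distance to the tumour border
#'
#' Assigns every voxel the exact Euclidean distance (mm, voxel centre to
#' voxel centre, honouring anisotropic spacing) to the nearest border voxel
#' of the mask. The sign is negative strictly inside the mask, zero on
#' border voxels, and positive outside, producing the radial distance scale
#' on which 1-mm annuli are defined.
#'
#' @param mask logical 3D array (the tumour mask, e.g. a GTV).
#' @param grid a [voxel_grid()].
#' @param source_mask_id optional identifier recorded for provenance.
#' @return An object of class `signed_distance_map` with elements `values`
#'   (numeric 3D array, mm), `grid` and `source_mask_id`.
#' @export
signed_distance_map <- function(mask, grid, source_mask_id = "mask") {
  check_volume(mask, grid, "mask")
  mask <- mask & TRUE
  n_in <- sum(mask)
  if (n_in == 0L) stop("no tumour: mask is empty")
  if (n_in == length(mask)) stop("no exterior: mask covers the whole grid")
  border <- mask_border(mask)
  d2 <- edt_squared_cpp(as.vector(border), grid$dims, grid$spacing)
  d <- array(sqrt(d2), grid$dims)
  d[mask & !border] <- -d[mask & !border]
  structure(
    list(values = d, grid = grid, source_mask_id = source_mask_id),
    class = "signed_distance_map"
  )
}

#' 1-mm annulus labels from a signed distance map
#'
#' Partitions voxels whose signed distance lies in the half-open window
#' `[d_min, d_max)` into 1-mm annuli. A voxel at distance `d` mm receives
#' the 0-based label `floor(d - d_min_mm)`; voxels outside the window get
#' `NA`. The window is given in cm (negative = inside the tumour border).
#'
#' @param sdm a [signed_distance_map()].
#' @param window numeric length 2, `(d_min, d_max)` in cm. The default
#'   `c(-0.5, 2)` spans tumour and peritumour (25 annuli); the dose window
#'   `c(0.5, 4)` yields 35 annuli.
#' @return An object of class `annulus_labels`: `labels` (integer 3D array,
#'   0-based, `NA` outside the window), `window` (cm), `n_annuli`,
#'   `centres_cm` (annulus centres in cm), `grid`.
#' @export
annulus_labels <- function(sdm, window = c(-0.5, 2)) {
  stopifnot(inherits(sdm, "signed_distance_map"), length(window) == 2L)
  if (window[2] <= window[1]) stop("annulus window must be ordered (d_min < d_max)")
  wmm <- window * 10
  n <- round(wmm[2] - wmm[1])
  if (n < 1 || abs((wmm[2] - wmm[1]) - n) > 1e-8) {
    stop("annulus window width must be a positive multiple of 1 mm")
  }
  lab <- floor(sdm$values - wmm[1])
  lab[sdm$values < wmm[1] | sdm$values >= wmm[2]] <- NA
  structure(
    list(labels = array(as.integer(lab), sdm$grid$dims),
         window = window,
         n_annuli = as.integer(n),
         centres_cm = (wmm[1] + seq_len(n) - 0.5) / 10,
         grid = sdm$grid),
    class = "annulus_labels"
  )
}

#' Number of 1-mm annuli in a radial window
#'
#' @param window numeric length 2 in cm.
#' @return Integer annulus count, `round(10 * diff(window))`.
#' @export
n_annuli <- function(window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  as.integer(round(10 * (window[2] - window[1])))
}

#' Annulus centre positions for a radial window
#'
#' @param window numeric length 2 in cm.
#' @return Numeric vector of annulus centres (cm), 0.5 mm into each bin.
#' @export
annulus_centres <- function(window) {
  n <- n_annuli(window)
  (window[1] * 10 + seq_len(n) - 0.5) / 10
}
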