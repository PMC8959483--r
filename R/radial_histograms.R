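#' Default value-bin edges
#'
#' Density histograms use 1-HU bins over the full CT range; dose histograms
#' use 0.1-Gy bins over 0-200 Gy EQD2, matching the granularities of the
#' near-zero-variance screen.
#'
#' @return Numeric vector of ordered bin edges.
#' @export
density_bin_edges <- function() seq(-1024, 3071, by = 1)

#' @rdname density_bin_edges
#' @export
dose_bin_edges <- function() seq(0, 200, by = 0.1)

#' Radial cross-histogram of value mass per annulus
#'
#' Builds the 2D "radial histogram": a table of tissue volume (mm^3) per
#' (value bin x 1-mm annulus), restricted to an anatomical mask. Density
#' histograms are restricted to lung-plus-tumour; dose histograms to the
#' body. Each in-window, in-restrict voxel contributes its physical volume
#' to the bin of its image value and the annulus of its distance label;
#' values outside the edge range are clamped into the end bins.
#'
#' @param image numeric 3D array of voxel values (HU or Gy).
#' @param labels an [annulus_labels()].
#' @param restrict logical 3D array; voxels outside it are ignored.
#' @param value_bin_edges ordered numeric bin edges (>= 2).
#' @param grid a [voxel_grid()] shared by all inputs.
#' @param restrict_mask_id provenance identifier of the restrict mask.
#' @return An object of class `radial_histogram`: `mass` (bins x annuli
#'   matrix, mm^3), `value_bin_edges`, `bin_centres`, `window` (cm),
#'   `centres_cm`, `restrict_mask_id`, `voxel_volume`.
#' @export
build_radial_histogram <- function(image, labels, restrict, value_bin_edges,
                                   grid, restrict_mask_id = "restrict") {
  stopifnot(inherits(labels, "annulus_labels"))
  check_volume(image, grid, "image")
  check_volume(restrict, grid, "restrict mask")
  if (!identical(labels$grid$dims, grid$dims)) {
    stop("annulus labels were computed on a different grid")
  }
  if (length(value_bin_edges) < 2L || is.unsorted(value_bin_edges, strictly = TRUE)) {
    stop("value_bin_edges must be >= 2 strictly increasing values")
  }
  nb <- length(value_bin_edges) - 1L
  na <- labels$n_annuli
  sel <- !is.na(labels$labels) & (restrict & TRUE)
  if (!any(sel)) {
    warning("restrict mask is empty inside the annulus window; histogram is all zero")
    mass <- matrix(0, nb, na)
  } else {
    v <- image[sel]
    bin <- findInterval(v, value_bin_edges)
    bin <- pmin(pmax(bin, 1L), nb)                # clamp to end bins
    ann <- labels$labels[sel] + 1L                # 1-based column
    counts <- tabulate(bin + nb * (ann - 1L), nbins = nb * na)
    mass <- matrix(counts, nb, na) * grid$voxel_volume
  }
  structure(
    list(mass = mass,
         value_bin_edges = value_bin_edges,
         bin_centres = (value_bin_edges[-1] + value_bin_edges[-(nb + 1L)]) / 2,
         window = labels$window,
         centres_cm = labels$centres_cm,
         restrict_mask_id = restrict_mask_id,
         voxel_volume = grid$voxel_volume),
    class = "radial_histogram"
  )
}

#' Crop a radial histogram to a narrower window
#'
#' Drops annulus columns outside the requested window; mass in retained
#' columns is untouched. The requested window must lie within the
#' histogram's window and align to the 1-mm annulus boundaries.
#'
#' @param h a `radial_histogram`.
#' @param window numeric length 2 in cm.
#' @return A cropped `radial_histogram`.
#' @export
crop_histogram <- function(h, window) {
  stopifnot(inherits(h, "radial_histogram"), length(window) == 2L)
  if (window[1] < h$window[1] - 1e-9 || window[2] > h$window[2] + 1e-9) {
    stop("requested window lies outside the histogram window")
  }
  off <- (window[1] - h$window[1]) * 10
  n <- (window[2] - window[1]) * 10
  if (abs(off - round(off)) > 1e-8 || abs(n - round(n)) > 1e-8 || round(n) < 1) {
    stop("crop window must align to 1-mm annulus boundaries")
  }
  keep <- round(off) + seq_len(round(n))
  h$mass <- h$mass[, keep, drop = FALSE]
  h$centres_cm <- h$centres_cm[keep]
  h$window <- window
  h
}

#' Total mass (mm^3) of a radial histogram
#' @param h a `radial_histogram`.
#' @return Scalar total tissue volume.
#' @export
histogram_mass <- function(h) sum(h$mass)

#' Write a radial histogram as a labelled CSV table
#'
#' @param h a `radial_histogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  df <- as.data.frame(h$mass)
  names(df) <- sprintf("annulus_%g_cm", h$centres_cm)
  df <- cbind(bin_centre = h$bin_centres, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
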