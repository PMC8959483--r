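#' Plot an interaction significance map
#'
#' Heatmap of -log10(p) over (density distance, dose distance), the usual
#' way these maps are read; missing cells are blank.
#'
#' @param x an `interaction_map`.
#' @param alpha contour level drawn at the significance threshold.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.interaction_map <- function(x, alpha = 0.05, ...) {
  z <- -log10(x$p_values)
  graphics::image(x$density_distances, x$dose_distances, z,
                  xlab = "density distance from GTV border (cm)",
                  ylab = "dose distance from GTV border (cm)",
                  main = sprintf("%s x %s", x$metric_pair[1],
                                 x$metric_pair[2]), ...)
  if (any(!is.na(x$p_values))) {
    graphics::contour(x$density_distances, x$dose_distances, z,
                      levels = -log10(alpha), add = TRUE, lwd = 2,
                      drawlabels = FALSE)
  }
  invisible(x)
}

#' Plot a hazard-ratio contrast curve
#'
#' ln(HR) against density at a fixed dose level, with its pointwise 95%
#' confidence band and the zero reference line.
#'
#' @param x a `contrast_curve`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.contrast_curve <- function(x, ...) {
  ylim <- range(c(x$ln_hr, x$ci_lo, x$ci_hi), na.rm = TRUE)
  graphics::plot(x$density_grid, x$ln_hr, type = "l", lwd = 2, ylim = ylim,
                 xlab = "density", ylab = "ln(HR) vs cohort mean",
                 main = sprintf("dose level %.3g", x$dose_value), ...)
  if (!all(is.na(x$ci_lo))) {
    graphics::lines(x$density_grid, x$ci_lo, lty = 2)
    graphics::lines(x$density_grid, x$ci_hi, lty = 2)
  }
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
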