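#' Spatial grid of stimulus-center offsets
#'
#' Square-center positions relative to the receptive-field center are binned
#' on a uniform grid, symmetric about zero. The default bin width of 0.2
#' degrees with centers from -3.4 to +3.4 degrees places exactly three bin
#' centers per side inside the edge band `1.7 < |x| < 2.3` used by the edge
#' response definition, and 25 bin centers inside the surface region
#' `|x| < 0.5, |y| < 0.5`.
#'
#' @param bin_width bin width in degrees of visual angle.
#' @param extent half-extent in degrees; centers run `-extent .. extent`.
#' @return object of class `spatial_grid` with `x_centers`, `y_centers`,
#'   `bin_width`.
#' @export
spatial_grid <- function(bin_width = 0.2, extent = 3.4) {
  stopifnot(bin_width > 0, extent > 0)
  n <- round(extent / bin_width)
  centers <- seq(-n, n) * bin_width
  structure(
    list(x_centers = centers, y_centers = centers, bin_width = bin_width),
    class = "spatial_grid"
  )
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf(
    "<spatial_grid> %d x %d bins, width %.2f deg, extent +/-%.1f deg\n",
    length(x$x_centers), length(x$y_centers), x$bin_width, max(x$x_centers)
  ))
  invisible(x)
}

## Indices of centers in the open edge band 1.7 < |c| < 2.3 (strict, applied
## to bin centers) and the open surface region |c| < 0.5.
edge_band_idx <- function(centers, inner = 1.7, outer = 2.3) {
  which(abs(centers) > inner & abs(centers) < outer)
}

surface_idx <- function(centers, half = 0.5) {
  which(abs(centers) < half)
}

check_grid_covers_edge_band <- function(grid) {
  if (length(edge_band_idx(grid$x_centers)) == 0L ||
      length(edge_band_idx(grid$y_centers)) == 0L) {
    config_error(
      "grid too small: no bin centers fall in the edge band 1.7 < |x| < 2.3"
    )
  }
  invisible(TRUE)
}
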