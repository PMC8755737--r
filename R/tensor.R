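#' Trial-averaged response tensor R(x, y, l, tau)
#'
#' Container for a site's trial-averaged MUA response as a function of the
#' square center's spatial offset from the receptive-field center (x, y, in
#' degrees), stimulus luminance label l (-1 black, 0 gray, +1 white) and
#' peristimulus time tau in milliseconds (tau = 0 at stimulus onset).
#'
#' @param values numeric 4-D array `[x, y, l, t]`, finite.
#' @param grid a [spatial_grid()] matching the first two dims.
#' @param luminance luminance labels for dim 3 (default `c(-1, 0, 1)`).
#' @param time time axis in ms for dim 4; must include at least 50 ms of
#'   pre-stimulus baseline.
#' @param layer cortical layer label, e.g. `"L4C"` or `"L2/3"`.
#' @param site_id site identifier.
#' @return object of class `response_tensor`.
#' @export
response_tensor <- function(values, grid, luminance = c(-1, 0, 1),
                            time, layer = "L4C", site_id = "site1") {
  stopifnot(inherits(grid, "spatial_grid"), is.array(values))
  d <- dim(values)
  if (length(d) != 4L) config_error("tensor values must be a 4-D array [x, y, l, t]")
  if (d[1] != length(grid$x_centers) || d[2] != length(grid$y_centers))
    config_error("tensor spatial dims do not match the grid")
  if (d[3] != length(luminance)) config_error("luminance axis length mismatch")
  if (d[4] != length(time)) config_error("time axis length mismatch")
  if (!all(is.finite(values))) config_error("tensor contains non-finite values")
  if (min(time) > -50) config_error("time axis must include a pre-stimulus window of >= 50 ms")
  structure(
    list(values = values, grid = grid, luminance = luminance,
         time = time, layer = layer, site_id = site_id),
    class = "response_tensor"
  )
}

#' @export
print.response_tensor <- function(x, ...) {
  cat(sprintf(
    "<response_tensor> site %s (%s): %d x %d positions, l in {%s}, tau %d..%d ms\n",
    x$site_id, x$layer, dim(x$values)[1], dim(x$values)[2],
    paste(x$luminance, collapse = ", "), min(x$time), max(x$time)
  ))
  invisible(x)
}

## Index of a luminance label on the tensor's luminance axis.
lum_idx <- function(tensor, l) {
  i <- match(l, tensor$luminance)
  if (is.na(i)) config_error(sprintf("luminance label %s not on tensor axis", l))
  i
}

## Default 1-ms time base tau in [-50, 300] ms.
default_time_axis <- function(t_min = -50, t_max = 300) seq(t_min, t_max)

## Logical mask over a tensor's time axis for a closed window [from, to] ms.
time_window <- function(time, from, to) time >= from & time <= to
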