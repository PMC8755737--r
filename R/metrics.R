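#' Edge response time course
#'
#' Sums the response tensor over the vertical-edge band
#' (`1.7 < |x| < 2.3`, `|y| < 0.5`) and over the horizontal-edge band (the
#' transposed set), and returns whichever orientation has the larger response
#' amplitude. Amplitude is the peak of the baseline-subtracted time course
#' over 0-300 ms; an exact tie is broken toward the vertical orientation.
#'
#' @param tensor a [response_tensor()].
#' @param l luminance label (-1, 0 or +1).
#' @return numeric time course `Ar_edge(l, tau)` over the tensor's time axis,
#'   with attributes `orientation` (`"vertical"` or `"horizontal"`),
#'   `vertical` and `horizontal` (both component time courses).
#' @export
extract_edge_response <- function(tensor, l) {
  check_grid_covers_edge_band(tensor$grid)
  li <- lum_idx(tensor, l)
  xb <- edge_band_idx(tensor$grid$x_centers)
  yb <- edge_band_idx(tensor$grid$y_centers)
  xs <- surface_idx(tensor$grid$x_centers)
  ys <- surface_idx(tensor$grid$y_centers)
  v <- apply(tensor$values[xb, ys, li, , drop = FALSE], 4, sum)
  h <- apply(tensor$values[xs, yb, li, , drop = FALSE], 4, sum)
  amp <- function(x) {
    bs <- baseline_subtract(x, tensor$time)
    max(bs[time_window(tensor$time, 0, 300)])
  }
  pick_v <- amp(v) >= amp(h)
  out <- if (pick_v) v else h
  structure(out,
            orientation = if (pick_v) "vertical" else "horizontal",
            vertical = v, horizontal = h)
}

#' Surface response time course
#'
#' Sums the response tensor over the surface region `|x| < 0.5, |y| < 0.5`
#' (square center over the receptive field).
#'
#' @inheritParams extract_edge_response
#' @return numeric time course `Ar_surface(l, tau)`.
#' @export
extract_surface_response <- function(tensor, l) {
  xs <- surface_idx(tensor$grid$x_centers)
  ys <- surface_idx(tensor$grid$y_centers)
  if (length(xs) == 0L || length(ys) == 0L)
    config_error("grid has no bin centers with |x| < 0.5 and |y| < 0.5")
  li <- lum_idx(tensor, l)
  apply(tensor$values[xs, ys, li, , drop = FALSE], 4, sum)
}

#' Normalize edge and surface responses by their shared maximum
#'
#' Both time courses are divided by the maximum of their concatenation, so
#' the larger of the two peaks at exactly 1 and relative response strengths
#' are comparable across sites and layers. Signed (below-zero) values are
#' retained: a negative dip maps to a negative normalized value.
#'
#' @param ar_edge,ar_surface absolute response time courses on a common axis.
#' @return list with `r_edge`, `r_surface` and the shared `scale`. If both
#'   inputs are all zero the normalized courses are flagged missing (`NA`).
#' @export
normalize_profile <- function(ar_edge, ar_surface) {
  stopifnot(length(ar_edge) == length(ar_surface))
  m <- max(c(ar_edge, ar_surface))
  if (!is.finite(m) || m <= 0) {
    warning("all-zero (or non-positive) responses: normalization undefined")
    na <- rep(NA_real_, length(ar_edge))
    return(list(r_edge = na, r_surface = na, scale = flagged_na("zero maximum")))
  }
  list(r_edge = ar_edge / m, r_surface = ar_surface / m, scale = m)
}

#' Subtract the pre-stimulus baseline
#'
#' Subtracts the mean of the -50-0 ms pre-stimulus window. Applied uniformly
#' before index computation so that suppression indices see signed lobes.
#'
#' @param x response time course.
#' @param time time axis in ms.
#' @export
baseline_subtract <- function(x, time) {
  pre <- time_window(time, -50, 0)
  if (!any(pre)) config_error("time axis has no -50..0 ms pre-stimulus window")
  x - mean(x[pre])
}

#' Signal-to-noise ratio of a response time course
#'
#' Sample variance over the signal window (0-300 ms after onset) divided by
#' sample variance over the blank window (0-50 ms before onset). A site is
#' considered to respond reliably when SNR > 3.
#'
#' @param x response time course.
#' @param time time axis in ms.
#' @return SNR with attribute `reliable` (logical). A zero blank variance
#'   returns `Inf` with a warning.
#' @export
snr <- function(x, time) {
  sig <- x[time_window(time, 0, 300)]
  blank <- x[time >= -50 & time < 0]
  if (length(sig) < 2L || length(blank) < 2L)
    config_error("need both a 0-300 ms signal window and a -50-0 ms blank window")
  vb <- stats::var(blank)
  if (vb == 0) {
    warning("zero blank variance: SNR undefined, returning Inf")
    return(structure(Inf, reliable = NA))
  }
  val <- stats::var(sig) / vb
  structure(val, reliable = val > 3)
}

#' Sustain index
#'
#' Ratio of the integrated response during 120-200 ms after stimulus onset to
#' the integrated response during 40-200 ms. Values near 1 indicate a late
#' increase or sustained response; values near 0 indicate strong adaptation.
#' The input is baseline-rectified (negative values clipped to 0) before
#' integration so the index stays in [0, 1].
#'
#' @param x response time course (baseline-subtracted or raw nonnegative).
#' @param time time axis in ms; must cover 40-200 ms.
#' @return SI in [0, 1], or flagged `NA` when the 40-200 ms integral is zero.
#' @export
sustain_index <- function(x, time) {
  if (min(time) > 40 || max(time) < 200)
    config_error("time axis must cover 40-200 ms for the sustain index")
  xr <- pmax(x, 0)
  ## half-open windows [40, 200) and [120, 200): the discrete sums then match
  ## the continuum integrals (a flat response gives 80/160 = 0.5 exactly)
  denom <- sum(xr[time >= 40 & time < 200])
  if (denom == 0) return(flagged_na("zero 40-200 ms integral"))
  sum(xr[time >= 120 & time < 200]) / denom
}

#' Surface/edge response ratio in a time window
#'
#' Mean surface response over the window divided by mean edge response over
#' the window. The canonical early window is 40-100 ms and the late window is
#' 120-180 ms after stimulus onset.
#'
#' @param r_surface,r_edge response time courses on a common axis.
#' @param time time axis in ms.
#' @param window length-2 numeric, window in ms.
#' @return the ratio, or flagged `NA` when the edge mean is non-positive.
#' @export
se_ratio <- function(r_surface, r_edge, time, window = c(40, 100)) {
  w <- time_window(time, window[1], window[2])
  if (!any(w)) config_error("window outside the time axis")
  e <- mean(r_edge[w])
  if (e <= 0) return(flagged_na("non-positive edge mean"))
  mean(r_surface[w]) / e
}

#' Filling-in strength
#'
#' Change of the surface/edge ratio through time: S/E over 120-180 ms minus
#' S/E over 40-100 ms. Positive values indicate a late gain of surface
#' response relative to edge response.
#'
#' @inheritParams se_ratio
#' @export
filling_in_strength <- function(r_surface, r_edge, time) {
  late <- se_ratio(r_surface, r_edge, time, c(120, 180))
  early <- se_ratio(r_surface, r_edge, time, c(40, 100))
  if (is.na(late) || is.na(early)) return(flagged_na("undefined window ratio"))
  late - early
}

#' Surface suppression index
#'
#' For a biphasic (reverse-correlation) surface response with an early
#' positive and a late negative lobe: the negative-lobe strength divided by
#' the total lobe strength, `N / (N + P)`, computed on the
#' baseline-relative time course within the analysis window (0-250 ms by
#' default). 0 means no suppression; values approach 1 when the negative
#' lobe dominates.
#'
#' @param x signed (baseline-subtracted) response time course.
#' @param time time axis in ms.
#' @param window analysis window in ms.
#' @return index in [0, 1], or flagged `NA` when both lobes are zero.
#' @export
surface_suppression_index <- function(x, time, window = c(0, 250)) {
  w <- time_window(time, window[1], window[2])
  if (!any(w)) config_error("window outside the time axis")
  xs <- x[w]
  p <- sum(xs[xs > 0])
  n <- abs(sum(xs[xs < 0]))
  if (p + n == 0) return(flagged_na("zero response"))
  n / (n + p)
}

#' Edge suppression index
#'
#' Fractional reduction of the square-edge response relative to the
#' frame-edge response: `(frame - square) / frame`, computed on
#' window-integrated response strengths. Positive values mean the edge of a
#' full square is suppressed relative to the same edge presented as an empty
#' frame.
#'
#' @param r_frame_edge,r_square_edge edge time courses from the same site on
#'   a common axis (baseline-subtracted).
#' @param time time axis in ms.
#' @param window integration window in ms.
#' @return the index (at most 1), or flagged `NA` for non-positive frame
#'   strength.
#' @export
edge_suppression_index <- function(r_frame_edge, r_square_edge, time,
                                   window = c(0, 250)) {
  w <- time_window(time, window[1], window[2])
  if (!any(w)) config_error("window outside the time axis")
  f <- sum(r_frame_edge[w])
  s <- sum(r_square_edge[w])
  if (f <= 0) return(flagged_na("non-positive frame edge strength"))
  (f - s) / f
}

#' Per-site scalar metrics for one luminance condition
#'
#' Convenience wrapper running the full metric set on a tensor: edge/surface
#' extraction, shared-max normalization, SNR, sustain indices, early/late S/E
#' ratios and filling-in strength.
#'
#' @param tensor a [response_tensor()].
#' @param l luminance label.
#' @return one-row `data.frame` of metrics.
#' @export
site_metrics <- function(tensor, l) {
  ar_e <- extract_edge_response(tensor, l)
  ar_s <- extract_surface_response(tensor, l)
  np <- normalize_profile(as.numeric(ar_e), ar_s)
  tm <- tensor$time
  bs_e <- baseline_subtract(np$r_edge, tm)
  bs_s <- baseline_subtract(np$r_surface, tm)
  data.frame(
    site_id = tensor$site_id,
    layer = tensor$layer,
    luminance = l,
    snr_edge = as.numeric(snr(np$r_edge, tm)),
    snr_surface = as.numeric(snr(np$r_surface, tm)),
    si_edge = as.numeric(sustain_index(bs_e, tm)),
    si_surface = as.numeric(sustain_index(bs_s, tm)),
    se_ratio_early = as.numeric(se_ratio(bs_s, bs_e, tm, c(40, 100))),
    se_ratio_late = as.numeric(se_ratio(bs_s, bs_e, tm, c(120, 180))),
    filling_in = as.numeric(filling_in_strength(bs_s, bs_e, tm)),
    stringsAsFactors = FALSE
  )
}
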