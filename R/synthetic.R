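#' Input-layer generator parameters
#'
#' Parameters of the synthetic input-layer (layer 4C) response generator.
#' Amplitudes are expressed as region-summed response amplitudes: the peak
#' of the extracted surface time course equals `surface_amplitude` and the
#' peak of the extracted edge time course equals `edge_amplitude` (for a
#' white stimulus; black amplitudes are `black_dominance` times larger).
#' The temporal waveform is a smooth transient-plus-plateau: a saturating
#' rise multiplied by a partial exponential decay, with independent latency,
#' rise and adaptation knobs. `adaptation_fraction` may be a scalar or a
#' length-2 vector `(surface, edge)`; the defaults make the edge drive more
#' transient than the surface drive, as in input-layer recordings.
#'
#' @param surface_amplitude,edge_amplitude nonnegative region-summed
#'   amplitudes (normalized response units, white stimulus).
#' @param onset_latency response latency in ms.
#' @param rise_time rise time constant in ms.
#' @param adaptation_fraction fraction of the response that decays away
#'   (0 = sustained plateau, 1 = fully transient); scalar or
#'   `c(surface, edge)`.
#' @param adaptation_tau decay time constant in ms.
#' @param black_dominance black/white response gain ratio, `>= 1`.
#' @param trial_noise_sd single-trial noise SD as a fraction of a site's
#'   peak response.
#' @export
input_layer_params <- function(surface_amplitude = 0.4, edge_amplitude = 1.0,
                               onset_latency = 30, rise_time = 8,
                               adaptation_fraction = c(surface = 0.3, edge = 0.6),
                               adaptation_tau = 80,
                               black_dominance = 1.2, trial_noise_sd = 0.2) {
  af <- rep_len(unname(adaptation_fraction), 2L)
  stopifnot(surface_amplitude >= 0, edge_amplitude >= 0,
            all(af >= 0), all(af <= 1),
            onset_latency >= 0, rise_time > 0, adaptation_tau > 0,
            black_dominance >= 1, trial_noise_sd >= 0)
  structure(
    list(surface_amplitude = surface_amplitude, edge_amplitude = edge_amplitude,
         onset_latency = onset_latency, rise_time = rise_time,
         adaptation_fraction = c(surface = af[1], edge = af[2]),
         adaptation_tau = adaptation_tau,
         black_dominance = black_dominance, trial_noise_sd = trial_noise_sd),
    class = "input_layer_params"
  )
}

## Step-response waveform, peak-normalized to 1 (zero before latency).
## A stimulus of finite duration drives the linear on/off difference
## step(tau) - step(tau - duration).
input_waveform <- function(time, latency, rise, af, tau_adapt, duration = Inf) {
  step <- function(tt) {
    s <- tt - latency
    out <- ifelse(s > 0,
                  (1 - exp(-s / rise)) * ((1 - af) + af * exp(-s / tau_adapt)),
                  0)
    out
  }
  w <- step(time)
  if (is.finite(duration)) w <- w - step(time - duration)
  m <- max(w)
  if (m > 0) w <- w / m
  w
}

#' Generate a synthetic input-layer response tensor
#'
#' Builds a trial-averaged R(x, y, l, tau) for a square (or frame) stimulus:
#' uniform surface drive over the square interior, edge drive over the edge
#' band `1.7 < max(|x|,|y|) < 2.3`, zero outside and zero for the gray
#' (blank) condition. Black responses equal white responses times
#' `black_dominance`. The tensor is deterministic (trial noise enters only
#' in [generate_trial_population()]).
#'
#' @param params an [input_layer_params()].
#' @param grid a [spatial_grid()]; must contain the edge band.
#' @param time time axis in ms (default 1-ms bins, -50..300).
#' @param duration stimulus duration in ms (300 flashed, 20
#'   reverse-correlation).
#' @param shape `"square"` (surface + edge drive) or `"frame"` (edge drive
#'   only, empty interior).
#' @param layer,site_id labels for the tensor.
#' @return a [response_tensor()].
#' @export
generate_input_layer_tensor <- function(params, grid = spatial_grid(),
                                        time = default_time_axis(),
                                        duration = 300, shape = c("square", "frame"),
                                        layer = "L4C", site_id = "synthetic_L4C") {
  shape <- match.arg(shape)
  stopifnot(inherits(params, "input_layer_params"), duration > 0)
  check_grid_covers_edge_band(grid)
  nx <- length(grid$x_centers); ny <- length(grid$y_centers)
  n_surf_bins <- length(surface_idx(grid$x_centers)) *
    length(surface_idx(grid$y_centers))
  ## vertical-edge-band bin count entering the edge sum (band x central y)
  n_edge_bins <- length(edge_band_idx(grid$x_centers)) *
    length(surface_idx(grid$y_centers))

  w_s <- input_waveform(time, params$onset_latency, params$rise_time,
                        params$adaptation_fraction["surface"],
                        params$adaptation_tau, duration)
  w_e <- input_waveform(time, params$onset_latency, params$rise_time,
                        params$adaptation_fraction["edge"],
                        params$adaptation_tau, duration)

  ax <- abs(grid$x_centers); ay <- abs(grid$y_centers)
  mx <- outer(ax, ay, pmax)
  interior <- mx < 1.7
  band <- mx > 1.7 & mx < 2.3
  s_map <- matrix(0, nx, ny)
  e_map <- matrix(0, nx, ny)
  if (shape == "square") s_map[interior] <- params$surface_amplitude / n_surf_bins
  e_map[band] <- params$edge_amplitude / n_edge_bins

  vals <- array(0, dim = c(nx, ny, 3L, length(time)))
  for (li in c(1L, 3L)) {            # black = 1, white = 3 on axis (-1, 0, 1)
    gain <- if (li == 1L) params$black_dominance else 1
    spatial <- gain * s_map
    spatial_e <- gain * e_map
    for (ti in seq_along(time)) {
      vals[, , li, ti] <- spatial * w_s[ti] + spatial_e * w_e[ti]
    }
  }
  response_tensor(vals, grid, luminance = c(-1, 0, 1), time = time,
                  layer = layer, site_id = site_id)
}

## Classify grid positions for the transmission-model gains.
position_class_1d <- function(x, y) {
  m <- pmax(abs(x), abs(y))
  ifelse(m < 1.7, "surface", "edge")
}

#' Transform an input-layer tensor through the transmission model
#'
#' Applies the 1-D laminar transmission model to the tensor, producing a
#' synthetic output-layer (layer 2/3) tensor. The model's spatial axis is
#' the axis perpendicular to the probed edge: bins with `|x| >= |y|`
#' (vertical-edge side) are computed by pooling along x within their y row,
#' bins with `|y| > |x|` (horizontal-edge side) by pooling along y within
#' their x column. With `model = "B"` and zero inhibitory gain the result
#' is bit-identical to the `model = "A"` forward pass.
#'
#' @param input_tensor a [response_tensor()] (input layer).
#' @param model_params a [transmission_params()], or a named list with
#'   elements `white` and `black` for polarity-specific parameters.
#' @param model `"B"` (excitation - inhibition) or `"A"` (excitation only).
#' @param layer,site_id labels for the output tensor.
#' @return a [response_tensor()] for the output layer.
#' @export
generate_output_layer_tensor <- function(input_tensor, model_params,
                                         model = c("B", "A"),
                                         layer = "L2/3",
                                         site_id = "synthetic_L23") {
  model <- match.arg(model)
  stopifnot(inherits(input_tensor, "response_tensor"))
  per_pol <- is.list(model_params) && !inherits(model_params, "transmission_params")
  if (per_pol && !all(c("white", "black") %in% names(model_params)))
    config_error("polarity-specific model_params need elements 'white' and 'black'")
  xs <- input_tensor$grid$x_centers
  ys <- input_tensor$grid$y_centers
  vals <- array(0, dim = dim(input_tensor$values))
  row_wedge <- outer(abs(xs), abs(ys), `>=`)   # TRUE: pool along x
  for (li in seq_along(input_tensor$luminance)) {
    l <- input_tensor$luminance[li]
    if (l == 0) next
    p <- if (per_pol) model_params[[if (l > 0) "white" else "black"]] else model_params
    for (yi in seq_along(ys)) {
      r_in <- input_tensor$values[, yi, li, ]
      if (all(r_in == 0)) next
      cls <- position_class_1d(xs, ys[yi])
      keep <- which(row_wedge[, yi])
      if (length(keep) == 0L) next
      vals[keep, yi, li, ] <- forward_components(
        r_in, xs, xs[keep], cls[keep], p, inhibition = (model == "B"))$out
    }
    for (xi in seq_along(xs)) {
      r_in <- input_tensor$values[xi, , li, ]
      if (all(r_in == 0)) next
      cls <- position_class_1d(xs[xi], ys)
      keep <- which(!row_wedge[xi, ])
      if (length(keep) == 0L) next
      vals[xi, keep, li, ] <- forward_components(
        r_in, ys, ys[keep], cls[keep], p, inhibition = (model == "B"))$out
    }
  }
  response_tensor(vals, input_tensor$grid, luminance = input_tensor$luminance,
                  time = input_tensor$time, layer = layer, site_id = site_id)
}

#' Extract the 1-D response profile along x
#'
#' Returns the tensor values along the x axis at the y row closest to 0, as
#' a `positions x time` matrix — the input format of the transmission-model
#' fitting functions.
#'
#' @param tensor a [response_tensor()].
#' @param l luminance label.
#' @return matrix with `length(x_centers)` rows; attribute `positions`.
#' @export
profile_along_x <- function(tensor, l) {
  li <- lum_idx(tensor, l)
  yi <- which.min(abs(tensor$grid$y_centers))
  m <- tensor$values[, yi, li, ]
  structure(m, positions = tensor$grid$x_centers)
}

#' Generate a single-trial population from a response tensor
#'
#' Emulates an aggregated (non-simultaneously recorded) population: each
#' synthetic site carries an overall log-normal gain and a log-normal
#' black/white preference around the tensor's mean asymmetry, and each trial
#' adds independent homoscedastic Gaussian noise. Trials cover every
#' luminance condition at both stimulus locations (square centered on the
#' receptive field = surface trials; square edge over the receptive field =
#' edge trials); gray trials are blanks with baseline noise only.
#'
#' @param tensor a [response_tensor()], or a list of tensors (one site
#'   each), in which case `n_sites` must not exceed the list length.
#' @param n_sites number of sites.
#' @param n_trials trials per (luminance x location) condition, `>= 2`.
#' @param noise_sd trial noise SD: a fraction of each site's peak mean
#'   response (`noise_scale = "fraction"`, default 0.2), or an absolute SD
#'   in response units scaled by the site gain
#'   (`noise_scale = "absolute"`).
#' @param noise_scale interpretation of `noise_sd`.
#' @param seed integer seed.
#' @param window response window in ms averaged into the decoding feature.
#' @param site_gain_sd SD of the per-site log-gain.
#' @param polarity_sd SD of the per-site log black/white preference; 0 makes
#'   every site share the tensor's asymmetry.
#' @param time_bins optional vector of bin edges in ms; when supplied the
#'   design also carries `x_time`, an array `trial x site x bin` of
#'   bin-averaged responses with independent noise per bin.
#' @param edge_position x offset (deg) probed for edge trials.
#' @return object of class `population_design` with fields `x`
#'   (`trial x site`), `luminance`, `location`, `n_trials`, `noise_sd`,
#'   `site_gains`, and optionally `x_time`/`bin_centers`.
#' @export
generate_trial_population <- function(tensor, n_sites = 32, n_trials = 50,
                                      noise_sd = 0.2, seed = 1,
                                      window = c(40, 250),
                                      site_gain_sd = 0.3, polarity_sd = 0.5,
                                      time_bins = NULL, edge_position = 2.0,
                                      noise_scale = c("fraction", "absolute")) {
  noise_scale <- match.arg(noise_scale)
  stopifnot(n_trials >= 2, noise_sd >= 0)
  tensors <- if (inherits(tensor, "response_tensor")) list(tensor) else tensor
  if (!inherits(tensor, "response_tensor")) {
    if (n_sites > length(tensors))
      stop("n_sites exceeds the number of available site tensors")
  }
  tref <- tensors[[1L]]
  tm <- tref$time
  wmask <- time_window(tm, window[1], window[2])
  xs <- tref$grid$x_centers
  x0 <- which.min(abs(xs)); y0 <- which.min(abs(tref$grid$y_centers))
  xe <- which.min(abs(xs - edge_position))

  ## condition-mean response in the window per (luminance, location)
  cond_mean <- function(tn, l, loc) {
    li <- lum_idx(tn, l)
    xi <- if (loc == "surface") x0 else xe
    mean(tn$values[xi, y0, li, wmask])
  }
  bin_mean <- function(tn, l, loc, lo, hi) {
    li <- lum_idx(tn, l)
    xi <- if (loc == "surface") x0 else xe
    mean(tn$values[xi, y0, li, tm >= lo & tm < hi])
  }

  lums <- c(-1, 0, 1)
  locs <- c("surface", "edge")
  cond <- expand.grid(luminance = lums, location = locs,
                      stringsAsFactors = FALSE)
  m <- nrow(cond) * n_trials
  lum_v <- rep(cond$luminance, each = n_trials)
  loc_v <- rep(cond$location, each = n_trials)

  with_seed(seed, {
    gains <- exp(rnorm(n_sites, 0, site_gain_sd))
    pref <- exp(rnorm(n_sites, 0, polarity_sd))
    site_src <- if (length(tensors) == 1L) rep(1L, n_sites) else
      sample.int(length(tensors), n_sites)

    mu <- matrix(0, m, n_sites)
    for (s in seq_len(n_sites)) {
      tn <- tensors[[site_src[s]]]
      base <- mapply(function(l, loc) cond_mean(tn, l, loc), lum_v, loc_v)
      mu[, s] <- gains[s] * base * pref[s]^lum_v
    }
    sds <- if (noise_scale == "fraction") {
      peak <- apply(abs(mu), 2, max)
      peak[peak == 0] <- 1
      noise_sd * peak
    } else {
      noise_sd * gains
    }
    X <- mu + matrix(rnorm(m * n_sites), m, n_sites) %*% diag(sds, n_sites)

    out <- list(x = X, luminance = lum_v, location = loc_v,
                n_trials = n_trials, noise_sd = noise_sd,
                site_gains = gains, site_pref = pref, seed = seed,
                window = window)
    if (!is.null(time_bins)) {
      nb <- length(time_bins) - 1L
      XT <- array(0, dim = c(m, n_sites, nb))
      for (bi in seq_len(nb)) {
        mu_b <- matrix(0, m, n_sites)
        for (s in seq_len(n_sites)) {
          tn <- tensors[[site_src[s]]]
          base <- mapply(function(l, loc)
            bin_mean(tn, l, loc, time_bins[bi], time_bins[bi + 1L]),
            lum_v, loc_v)
          mu_b[, s] <- gains[s] * base * pref[s]^lum_v
        }
        XT[, , bi] <- mu_b + matrix(rnorm(m * n_sites), m, n_sites) %*% diag(sds, n_sites)
      }
      out$x_time <- XT
      out$bin_centers <- (head(time_bins, -1L) + time_bins[-1L]) / 2
      out$time_bins <- time_bins
    }
    structure(out, class = "population_design")
  })
}

#' @export
print.population_design <- function(x, ...) {
  cat(sprintf("<population_design> %d trials x %d sites, %d trials/condition, noise_sd %.3g\n",
              nrow(x$x), ncol(x$x), x$n_trials, x$noise_sd))
  invisible(x)
}

#' Subset a population design by labels
#'
#' @param design a `population_design`.
#' @param location optional location label(s) to keep.
#' @param luminance optional luminance label(s) to keep.
#' @export
design_subset <- function(design, location = NULL, luminance = NULL) {
  keep <- rep(TRUE, nrow(design$x))
  if (!is.null(location)) keep <- keep & design$location %in% location
  if (!is.null(luminance)) keep <- keep & design$luminance %in% luminance
  out <- design
  out$x <- design$x[keep, , drop = FALSE]
  out$luminance <- design$luminance[keep]
  out$location <- design$location[keep]
  if (!is.null(design$x_time)) out$x_time <- design$x_time[keep, , , drop = FALSE]
  out
}

#' Generate a reverse-correlation dataset (square and frame stimuli)
#'
#' Builds the 20-ms-pulse analogue of the flashed experiment: input-layer
#' tensors for a full square (surface + edge drive) and an empty frame (edge
#' drive only, interior exactly zero), plus their output-layer transforms
#' under the transmission model. The pair supports the suppression-index
#' analyses (biphasic surface response; square edge vs frame edge).
#'
#' @param input_params an [input_layer_params()].
#' @param model_params a [transmission_params()] or polarity list, as in
#'   [generate_output_layer_tensor()].
#' @param grid a [spatial_grid()].
#' @param time time axis in ms.
#' @param duration stimulus duration in ms (default 20).
#' @param model forward model for the output layer.
#' @return list with elements `square` and `frame`, each a list
#'   `input`/`output` of [response_tensor()]s, and `ground_truth`.
#' @export
generate_reverse_correlation_dataset <- function(input_params, model_params,
                                                 grid = spatial_grid(),
                                                 time = default_time_axis(),
                                                 duration = 20,
                                                 model = c("B", "A")) {
  model <- match.arg(model)
  sq_in <- generate_input_layer_tensor(input_params, grid, time, duration,
                                       shape = "square",
                                       site_id = "synthetic_L4C_square")
  fr_in <- generate_input_layer_tensor(input_params, grid, time, duration,
                                       shape = "frame",
                                       site_id = "synthetic_L4C_frame")
  list(
    square = list(input = sq_in,
                  output = generate_output_layer_tensor(sq_in, model_params, model,
                                                        site_id = "synthetic_L23_square")),
    frame = list(input = fr_in,
                 output = generate_output_layer_tensor(fr_in, model_params, model,
                                                       site_id = "synthetic_L23_frame")),
    ground_truth = ground_truth(input_params, model_params, seed = NA_integer_,
                                n_trials = NA_integer_)
  )
}

#' Ground-truth record for a synthetic dataset
#'
#' @param input_params an [input_layer_params()].
#' @param model_params transmission parameters used for the output layer.
#' @param seed integer seed the dataset was generated with.
#' @param n_trials trials per condition.
#' @export
ground_truth <- function(input_params, model_params, seed, n_trials) {
  structure(
    list(input_params = input_params, model_params = model_params,
         seed = seed, n_trials = n_trials),
    class = "ground_truth"
  )
}

#' Default study ground truth
#'
#' The reference synthetic regime: default input-layer parameters, and
#' polarity-specific model-B parameters with nonlocal inhibition — spatial
#' extents sigma_I = 2 sigma_E (white 0.80/0.40 deg, black 0.53/0.27 deg, as
#' estimated for macaque V1 output layers) and inhibitory gains calibrated
#' in closed form so that the surface-site I/E ratio equals 1.1 (white) and
#' 0.74 (black), with edge-site inhibition at half those values (inhibition
#' is driven mainly by the surface, so edge-responding sites carry clearly
#' weaker fitted inhibition).
#'
#' @param input_params an [input_layer_params()].
#' @param grid a [spatial_grid()].
#' @param time time axis in ms.
#' @return list with `input_params`, `input_tensor`, `model_params`
#'   (`list(white, black)`), `target_ie`.
#' @export
default_ground_truth <- function(input_params = input_layer_params(),
                                 grid = spatial_grid(),
                                 time = default_time_axis()) {
  input <- generate_input_layer_tensor(input_params, grid, time)
  target_ie <- c(white = 1.1, black = 0.74)
  edge_ie_fraction <- 0.5
  sig <- list(white = c(e = 0.40, i = 0.80), black = c(e = 0.265, i = 0.53))
  mp <- lapply(c(white = "white", black = "black"), function(pol) {
    l <- if (pol == "white") 1 else -1
    base <- transmission_params(sigma_e = unname(sig[[pol]]["e"]),
                                sigma_i = unname(sig[[pol]]["i"]),
                                w_e_surface = 1, w_e_edge = 1, w_i = 1)
    prof <- profile_along_x(input, l)
    pos <- attr(prof, "positions")
    p <- calibrate_wi(base, prof, pos, target_ie[[pol]],
                      out_position = 0, out_class = "surface")
    calibrate_wi(p, prof, pos, edge_ie_fraction * target_ie[[pol]],
                 out_position = 2, out_class = "edge")
  })
  list(input_params = input_params, input_tensor = input,
       model_params = mp, target_ie = target_ie,
       edge_ie_fraction = edge_ie_fraction)
}
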