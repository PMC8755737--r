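#' Temporal kernel parameters
#'
#' A log-Gaussian signal-transfer kernel
#' `K(t) = exp(-(log(t) - delay)^2 / (2 sigma^2))`, evaluated on integer
#' lags t = 1..250 ms and normalized to unit sum so that the pathway gains
#' carry all amplitude scaling. The kernel mode sits at `t = exp(delay)` ms.
#'
#' @param delay kernel delay in log-ms, in `[0, 6]`.
#' @param sigma kernel width in log-ms, positive.
#' @export
kernel_params <- function(delay, sigma) {
  stopifnot(is.finite(delay), is.finite(sigma), sigma > 0)
  structure(list(delay = delay, sigma = sigma), class = "kernel_params")
}

#' Evaluate a temporal kernel on its support
#'
#' @param kp a [kernel_params()].
#' @param support integer lags in ms (default 1..250).
#' @param normalize normalize to unit sum (default TRUE).
#' @return numeric kernel values over `support`.
#' @export
temporal_kernel <- function(kp, support = 1:250, normalize = TRUE) {
  k <- exp(-(log(support) - kp$delay)^2 / (2 * kp$sigma^2))
  if (!all(is.finite(k))) stop("non-finite kernel values")
  if (normalize) {
    s <- sum(k)
    if (s == 0) stop("kernel sums to zero on its support")
    k <- k / s
  }
  k
}

#' Transmission-model parameters
#'
#' Parameters of the laminar signal-transmission models. Model A pools
#' excitation from the input layer through a Gaussian spatial kernel of
#' extent `sigma_e` (degrees) and a log-Gaussian temporal kernel, with
#' position-dependent gain (`w_e_surface` for sites whose receptive field
#' lies under the square interior, `w_e_edge` for sites under the edge).
#' Model B subtracts a nonlocal inhibitory pathway with its own spatial
#' extent `sigma_i`, temporal kernel and gain `w_i`; `w_i = 0` (with no
#' separate edge gain) reduces model B to model A exactly. Because the
#' pathway gains carry a site index in the model formulation, an optional
#' `w_i_edge` lets edge-class sites receive a different inhibitory gain
#' than surface-class sites (inhibition is driven mainly by the surface);
#' when `NULL` a single `w_i` applies everywhere, which is also the form
#' used in fitting. `a` and `b` mix two input-layer subdivisions when a
#' second input component is supplied.
#'
#' @param sigma_e,sigma_i spatial pooling extents in degrees, positive.
#' @param w_e_surface,w_e_edge,w_i nonnegative gains.
#' @param w_i_edge optional inhibitory gain for edge-class sites (`NULL` =
#'   use `w_i`).
#' @param kernel_e,kernel_i [kernel_params()] for each pathway.
#' @param a,b input-mixing weights.
#' @export
transmission_params <- function(sigma_e = 0.4, sigma_i = 0.8,
                                w_e_surface = 1, w_e_edge = 1, w_i = 1,
                                kernel_e = kernel_params(log(5), 0.3),
                                kernel_i = kernel_params(log(15), 0.4),
                                a = 1, b = 0, w_i_edge = NULL) {
  stopifnot(sigma_e > 0, sigma_i > 0,
            w_e_surface >= 0, w_e_edge >= 0, w_i >= 0,
            is.null(w_i_edge) || w_i_edge >= 0,
            inherits(kernel_e, "kernel_params"), inherits(kernel_i, "kernel_params"))
  structure(
    list(sigma_e = sigma_e, sigma_i = sigma_i,
         w_e_surface = w_e_surface, w_e_edge = w_e_edge, w_i = w_i,
         w_i_edge = w_i_edge,
         kernel_e = kernel_e, kernel_i = kernel_i, a = a, b = b),
    class = "transmission_params"
  )
}

#' @export
print.transmission_params <- function(x, ...) {
  cat(sprintf(
    paste0("<transmission_params> sigma_E %.3f deg, sigma_I %.3f deg, ",
           "wE(surface/edge) %.3f/%.3f, wI %.3f\n"),
    x$sigma_e, x$sigma_i, x$w_e_surface, x$w_e_edge, x$w_i))
  cat(sprintf("  kernel E: delay %.3f (mode %.1f ms) sigma %.3f; kernel I: delay %.3f (mode %.1f ms) sigma %.3f\n",
              x$kernel_e$delay, exp(x$kernel_e$delay), x$kernel_e$sigma,
              x$kernel_i$delay, exp(x$kernel_i$delay), x$kernel_i$sigma))
  invisible(x)
}

#' Gaussian spatial pooling
#'
#' Weighted sum of input-layer responses over site positions with Gaussian
#' weights `exp(-(j - i)^2 / (2 sigma^2))` centered on the target site.
#'
#' @param r_in matrix `sites x time` of input-layer responses.
#' @param positions site positions `j` in degrees (length = nrow(r_in)).
#' @param center target position `i` in degrees.
#' @param sigma pooling extent in degrees, positive.
#' @return pooled time course (numeric vector).
#' @export
spatial_pool <- function(r_in, positions, center, sigma) {
  if (is.null(dim(r_in))) r_in <- matrix(r_in, nrow = length(positions))
  if (nrow(r_in) == 0L) stop("empty site set")
  stopifnot(length(positions) == nrow(r_in), sigma > 0)
  w <- exp(-(positions - center)^2 / (2 * sigma^2))
  as.numeric(crossprod(w, r_in))
}

## Pooling for several target positions at once: returns n_out x T matrix.
pool_matrix <- function(r_in, positions, out_positions, sigma) {
  W <- outer(out_positions, positions,
             function(i, j) exp(-(j - i)^2 / (2 * sigma^2)))
  W %*% r_in
}

#' Causal temporal transfer (convolution with a unit-sum kernel)
#'
#' Convolves a signal with a temporal kernel evaluated on lags 1..250 ms,
#' with t = 1 acting instantaneously (lag 0), so a delta kernel at t = 1 is
#' the identity. Output has the same length as the input.
#'
#' @param signal numeric time course (1-ms bins).
#' @param kernel a [kernel_params()] or a numeric kernel vector.
#' @export
temporal_transfer <- function(signal, kernel) {
  k <- if (inherits(kernel, "kernel_params")) temporal_kernel(kernel) else kernel
  if (!all(is.finite(k))) stop("non-finite kernel values")
  drop(conv_rows(matrix(signal, nrow = 1), k))
}

## FFT causal convolution of each row of M with kernel k (lag s-1 for k[s]).
conv_rows <- function(M, k) {
  Tn <- ncol(M)
  K <- length(k)
  n2 <- stats::nextn(Tn + K - 1L, 2)
  fk <- stats::fft(c(k, rep(0, n2 - K)))
  Mp <- cbind(M, matrix(0, nrow(M), n2 - Tn))
  out <- Re(t(stats::mvfft(stats::mvfft(t(Mp)) * fk, inverse = TRUE))) / n2
  out[, seq_len(Tn), drop = FALSE]
}

## Shared forward pass: returns list(E, I, out) matrices n_out x T.
forward_components <- function(r_input, positions, out_positions, out_class,
                               params, inhibition = TRUE) {
  stopifnot(length(out_class) == length(out_positions))
  if (is.list(r_input) && !is.null(r_input$alpha)) {
    r_in <- params$a * r_input$alpha +
      if (!is.null(r_input$beta)) params$b * r_input$beta else 0
  } else {
    r_in <- r_input
  }
  if (is.null(dim(r_in))) r_in <- matrix(r_in, nrow = length(positions))
  gains <- ifelse(out_class == "surface", params$w_e_surface, params$w_e_edge)
  wie <- if (is.null(params$w_i_edge)) params$w_i else params$w_i_edge
  gains_i <- ifelse(out_class == "surface", params$w_i, wie)
  E <- conv_rows(pool_matrix(r_in, positions, out_positions, params$sigma_e),
                 temporal_kernel(params$kernel_e)) * gains
  if (inhibition && any(gains_i > 0)) {
    I <- conv_rows(pool_matrix(r_in, positions, out_positions, params$sigma_i),
                   temporal_kernel(params$kernel_i)) * gains_i
  } else {
    I <- matrix(0, nrow(E), ncol(E))
  }
  list(E = E, I = I, out = E - I)
}

#' Forward model A: pooled excitation only
#'
#' Output-layer response generated purely by Gaussian pooling of input-layer
#' excitation followed by the excitatory temporal kernel and a
#' position-class gain. Any inhibitory parameters in `params` are ignored.
#'
#' @param r_input matrix `sites x time` of input-layer responses (or a list
#'   with components `alpha`/`beta` mixed by `params$a`, `params$b`).
#' @param positions input site positions in degrees.
#' @param out_positions positions of the predicted output-layer sites.
#' @param out_class `"surface"` or `"edge"` per output position (selects the
#'   excitatory gain).
#' @param params a [transmission_params()].
#' @return matrix `length(out_positions) x time` of predicted responses.
#' @export
forward_model_a <- function(r_input, positions, out_positions, out_class, params) {
  forward_components(r_input, positions, out_positions, out_class, params,
                     inhibition = FALSE)$out
}

#' Forward model B: pooled excitation minus nonlocal inhibition
#'
#' As model A, plus a subtractive inhibitory pathway pooling the same input
#' with extent `sigma_i` and its own temporal kernel and gain. The output may
#' be negative; no rectification is applied.
#'
#' @inheritParams forward_model_a
#' @return matrix `length(out_positions) x time`.
#' @export
forward_model_b <- function(r_input, positions, out_positions, out_class, params) {
  forward_components(r_input, positions, out_positions, out_class, params,
                     inhibition = TRUE)$out
}

#' Adjusted goodness of fit between a data and a fitted time course
#'
#' `1 - (2 * SS_res / (T * (var(data) + var(fit)))) * (T - 1) / (T - pn)`,
#' where `pn` is the number of free model parameters and the variances are
#' population variances (divide by T). Equals 1 for a perfect fit and is
#' penalized by parameter count.
#'
#' @param r_data,r_fit time courses of equal length T (`T > pn`).
#' @param pn number of free parameters.
#' @param var_type `"population"` (default) or `"sample"`.
#' @return the goodness of fit (at most 1), or flagged `NA` when both
#'   series have zero variance.
#' @export
goodness_of_fit <- function(r_data, r_fit, pn, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  Tn <- length(r_data)
  stopifnot(length(r_fit) == Tn, Tn > pn)
  v <- function(x) if (var_type == "population") mean((x - mean(x))^2) else stats::var(x)
  denom <- v(r_data) + v(r_fit)
  if (denom == 0) return(flagged_na("zero variance in data and fit"))
  1 - (2 * sum((r_data - r_fit)^2) / (Tn * denom)) * (Tn - 1) / (Tn - pn)
}

## --- fitting ----------------------------------------------------------------

## Parameter vector layout for the optimizer.
theta_layout <- function(model, sigma_i_fixed = NULL) {
  if (model == "A") {
    nm <- c("sigma_e", "w_e_surface", "w_e_edge", "delay_e", "tsig_e")
  } else {
    nm <- c("sigma_e", "w_e_surface", "w_e_edge", "delay_e", "tsig_e",
            "w_i", "delay_i", "tsig_i")
    if (is.null(sigma_i_fixed)) nm <- c(nm, "sigma_i")
  }
  nm
}

theta_bounds <- function(names) {
  lower <- c(sigma_e = 0.05, sigma_i = 0.05, w_e_surface = 0, w_e_edge = 0,
             w_i = 0, delay_e = 0, delay_i = 0, tsig_e = 0.05, tsig_i = 0.05)
  upper <- c(sigma_e = 3, sigma_i = 3, w_e_surface = 10, w_e_edge = 10,
             w_i = 10, delay_e = 6, delay_i = 6, tsig_e = 3, tsig_i = 3)
  list(lower = unname(lower[names]), upper = unname(upper[names]))
}

theta_to_params <- function(theta, names, model, sigma_i_fixed = NULL) {
  p <- as.list(theta)
  names(p) <- names
  transmission_params(
    sigma_e = p$sigma_e,
    sigma_i = if (model == "A") 1 else if (is.null(sigma_i_fixed)) p$sigma_i else sigma_i_fixed,
    w_e_surface = p$w_e_surface, w_e_edge = p$w_e_edge,
    w_i = if (model == "A") 0 else p$w_i,
    kernel_e = kernel_params(p$delay_e, p$tsig_e),
    kernel_i = if (model == "A") kernel_params(log(15), 0.4)
               else kernel_params(p$delay_i, p$tsig_i)
  )
}

#' Fit a transmission model to output-layer time courses
#'
#' Bounded nonlinear least squares — Levenberg-Marquardt on the residual
#' vector with seeded random multistarts — minimizing the mean squared error
#' between the model prediction and the target time courses, fit jointly
#' with shared temporal kernels and position-class excitatory gains. The
#' default target is a surface and an edge time course at positions 0 and 2
#' degrees; alternatively a full response *profile* (one time course per
#' output position, as in a position-resolved response tensor) can be fit
#' by passing `target`, `out_positions` and `out_class` — the spatial decay
#' across positions then pins the pooling extents much more sharply than
#' two sites can.
#'
#' @param r_input matrix `sites x time` of input-layer responses.
#' @param positions input site positions in degrees.
#' @param target_surface,target_edge target output-layer time courses
#'   (same time base as `r_input` columns); ignored when `target` is given.
#' @param model `"A"` (excitation only) or `"B"` (excitation - inhibition).
#' @param out_positions positions of the predicted sites, default `c(0, 2)`
#'   degrees.
#' @param n_starts number of optimizer restarts.
#' @param seed integer seed for the restart draws.
#' @param sigma_i_fixed optionally clamp the inhibitory extent (used by
#'   [inhibition_range_scan()]).
#' @param maxit Levenberg-Marquardt iteration cap per start.
#' @param init optional named list of starting values overriding the default
#'   first start.
#' @param target optional `length(out_positions) x time` matrix of target
#'   time courses (profile mode).
#' @param out_class position class (`"surface"`/`"edge"`) per output
#'   position; defaults to `c("surface", "edge")` in two-course mode and to
#'   the square geometry (`"surface"` where `max|x| < 1.7`) in profile mode.
#' @return object of class `transmission_fit`: `params`, `model`, `pn`,
#'   `objective` (MSE), `predicted` (positions x T matrix), `gof_surface`,
#'   `gof_edge` (means over the positions of each class), `gof` (mean over
#'   all positions), `convergence`, `starts`.
#' @export
fit_model <- function(r_input, positions, target_surface = NULL,
                      target_edge = NULL, model = c("B", "A"),
                      out_positions = c(0, 2), n_starts = 10, seed = 1,
                      sigma_i_fixed = NULL, maxit = 300, init = NULL,
                      target = NULL, out_class = NULL) {
  model <- match.arg(model)
  if (is.null(dim(r_input))) r_input <- matrix(r_input, nrow = length(positions))
  Tn <- ncol(r_input)
  if (is.null(target)) {
    stopifnot(length(target_surface) == Tn, length(target_edge) == Tn)
    target <- rbind(target_surface, target_edge)
    if (is.null(out_class)) out_class <- c("surface", "edge")
  } else {
    target <- as.matrix(target)
    stopifnot(ncol(target) == Tn, nrow(target) == length(out_positions))
    if (is.null(out_class))
      out_class <- ifelse(abs(out_positions) < 1.7, "surface", "edge")
  }
  stopifnot(length(out_class) == nrow(target),
            length(out_positions) == nrow(target))
  nm <- theta_layout(model, sigma_i_fixed)
  b <- theta_bounds(nm)

  residuals_fn <- function(theta) {
    p <- tryCatch(theta_to_params(theta, nm, model, sigma_i_fixed),
                  error = function(e) NULL)
    if (is.null(p)) return(rep(1e5, length(target)))
    pred <- forward_components(r_input, positions, out_positions, out_class,
                               p, inhibition = (model == "B"))$out
    as.numeric(pred - target)
  }
  objective <- function(theta) mean(residuals_fn(theta)^2)

  default_start <- c(sigma_e = 0.4, w_e_surface = 0.5, w_e_edge = 0.5,
                     delay_e = log(5), tsig_e = 0.3,
                     w_i = 0.3, delay_i = log(15), tsig_i = 0.4, sigma_i = 0.8)
  base <- unname(default_start[nm])
  ## `init` may be one named list of starting values or a list of several;
  ## each yields one start (missing entries fall back to the default start)
  inits <- if (is.null(init)) list()
           else if (is.list(init[[1]])) init else list(init)
  starts <- lapply(inits, function(iv) {
    s <- base
    ov <- match(names(iv), nm)
    s[ov[!is.na(ov)]] <- unlist(iv)[!is.na(ov)]
    s
  })
  starts <- c(starts, list(base))
  n_rand <- max(0L, n_starts - length(starts))
  if (n_rand > 0) {
    rand <- with_seed(seed, {
      replicate(n_rand,
                b$lower + runif(length(nm)) * (b$upper - b$lower),
                simplify = FALSE)
    })
    starts <- c(starts, rand)
  }

  ## bounded Levenberg-Marquardt on the residual vector per start
  run_lm <- function(start) {
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = start, fn = residuals_fn,
        lower = b$lower, upper = b$upper,
        control = minpack.lm::nls.lm.control(
          maxiter = maxit, ftol = 1e-14, ptol = 1e-14, gtol = 0))
      list(par = fit$par, value = objective(fit$par), convergence = fit$info)
    }, error = function(e) NULL)
  }
  best <- NULL
  diag_tbl <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    res <- run_lm(starts[[s]])
    diag_tbl[[s]] <- if (is.null(res)) list(value = NA_real_, convergence = NA_integer_)
                     else list(value = res$value, convergence = res$convergence)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")

  params <- theta_to_params(best$par, nm, model, sigma_i_fixed)
  pred <- forward_components(r_input, positions, out_positions, out_class,
                             params, inhibition = (model == "B"))$out
  pn <- length(nm)
  gof_rows <- vapply(seq_len(nrow(target)), function(i)
    as.numeric(goodness_of_fit(target[i, ], pred[i, ], pn)), numeric(1))
  structure(
    list(params = params, model = model, pn = pn,
         objective = best$value, predicted = pred,
         out_positions = out_positions, out_class = out_class,
         gof_surface = mean(gof_rows[out_class == "surface"], na.rm = TRUE),
         gof_edge = mean(gof_rows[out_class == "edge"], na.rm = TRUE),
         gof = mean(gof_rows, na.rm = TRUE), gof_rows = gof_rows,
         convergence = best$convergence, starts = diag_tbl),
    class = "transmission_fit"
  )
}

#' @export
print.transmission_fit <- function(x, ...) {
  cat(sprintf("<transmission_fit> model %s: GoF %.3f (surface %.3f, edge %.3f), MSE %.4g, pn %d\n",
              x$model, x$gof, x$gof_surface, x$gof_edge, x$objective, x$pn))
  print(x$params)
  invisible(x)
}

#' Goodness of fit as a function of the inhibitory spatial extent
#'
#' Refits model B with the inhibitory extent clamped at each grid value; all
#' other parameters are free, and each grid point is warm-started from the
#' previous point's optimum in addition to its random restarts. On
#' well-posed synthetic data the curve peaks at the generating extent.
#'
#' @inheritParams fit_model
#' @param sigma_i_grid grid of inhibitory extents in degrees.
#' @param n_starts restarts per grid point.
#' @return `data.frame` with `sigma_i`, `gof`, `objective`; the attribute
#'   `best` holds the grid argmax of `gof`.
#' @export
inhibition_range_scan <- function(r_input, positions, target_surface = NULL,
                                  target_edge = NULL, sigma_i_grid,
                                  out_positions = c(0, 2),
                                  n_starts = 3, seed = 1, maxit = 300,
                                  init = NULL, target = NULL,
                                  out_class = NULL) {
  seeds <- derive_seeds(seed, length(sigma_i_grid))
  rows <- vector("list", length(sigma_i_grid))
  anchor <- if (!is.null(init) && !is.list(init[[1]])) list(init) else init
  prev <- NULL
  for (g in seq_along(sigma_i_grid)) {
    fit <- fit_model(r_input, positions, target_surface, target_edge,
                     model = "B", out_positions = out_positions,
                     n_starts = n_starts, seed = seeds[g],
                     sigma_i_fixed = sigma_i_grid[g], maxit = maxit,
                     init = c(anchor, prev), target = target,
                     out_class = out_class)
    p <- fit$params
    prev <- list(list(sigma_e = p$sigma_e, w_e_surface = p$w_e_surface,
                      w_e_edge = p$w_e_edge, delay_e = p$kernel_e$delay,
                      tsig_e = p$kernel_e$sigma, w_i = p$w_i,
                      delay_i = p$kernel_i$delay, tsig_i = p$kernel_i$sigma))
    rows[[g]] <- data.frame(sigma_i = sigma_i_grid[g], gof = fit$gof,
                            objective = fit$objective)
  }
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$sigma_i[which.max(out$gof)]
  out
}

#' Inhibition-to-excitation ratio of a fitted model
#'
#' Ratio of the time-integrated absolute inhibitory drive to the
#' time-integrated absolute pooled excitatory drive at a given output
#' position, for the supplied input.
#'
#' @inheritParams forward_model_b
#' @param out_position single output position in degrees.
#' @param out_class `"surface"` or `"edge"` for the excitatory gain.
#' @param window integration window in ms over the columns of `r_input`
#'   (requires `time`); `NULL` integrates the full time axis.
#' @param time optional time axis matching the input columns.
#' @return the I/E ratio (0 when `w_i = 0`), or flagged `NA` when the
#'   excitatory drive is zero.
#' @export
ie_ratio <- function(params, r_input, positions, out_position = 0,
                     out_class = "surface", window = NULL, time = NULL) {
  fc <- forward_components(r_input, positions, out_position, out_class, params)
  keep <- if (!is.null(window)) {
    stopifnot(!is.null(time), length(time) == ncol(fc$E))
    time_window(time, window[1], window[2])
  } else rep(TRUE, ncol(fc$E))
  e <- sum(abs(fc$E[1, keep]))
  if (e == 0) return(flagged_na("zero excitatory drive"))
  sum(abs(fc$I[1, keep])) / e
}

#' Calibrate an inhibitory gain to a target I/E ratio
#'
#' The I/E ratio at a site is exactly proportional to that site class's
#' inhibitory gain, so the gain achieving a target ratio for a given input
#' is a closed-form solve. With `out_class = "surface"` the shared gain
#' `w_i` is set; with `out_class = "edge"` the edge-specific `w_i_edge`.
#'
#' @inheritParams ie_ratio
#' @param target_ie desired I/E ratio.
#' @return a [transmission_params()] with the relevant gain replaced.
#' @export
calibrate_wi <- function(params, r_input, positions, target_ie,
                         out_position = 0, out_class = "surface") {
  probe <- params
  if (out_class == "surface") probe$w_i <- 1 else probe$w_i_edge <- 1
  base <- ie_ratio(probe, r_input, positions, out_position, out_class)
  if (is.na(base) || base == 0) stop("cannot calibrate: zero drive")
  gain <- target_ie / as.numeric(base)
  if (out_class == "surface") params$w_i <- gain else params$w_i_edge <- gain
  params
}
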