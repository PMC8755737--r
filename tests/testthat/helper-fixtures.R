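## Shared fixtures, all built in code.

default_grid <- spatial_grid()
default_time <- default_time_axis()

## Tensor with a chosen time course on the vertical-edge band, the
## horizontal-edge band and the surface region (per-bin values).
make_band_tensor <- function(edge_v = 0, edge_h = 0, surface = 0,
                             grid = default_grid, time = default_time,
                             luminance = c(-1, 0, 1), l_fill = 1) {
  as_course <- function(v) if (length(v) == 1L) rep(v, length(time)) else v
  ev <- as_course(edge_v); eh <- as_course(edge_h); sv <- as_course(surface)
  nx <- length(grid$x_centers); ny <- length(grid$y_centers)
  vals <- array(0, dim = c(nx, ny, length(luminance), length(time)))
  xb <- abs(grid$x_centers) > 1.7 & abs(grid$x_centers) < 2.3
  xc <- abs(grid$x_centers) < 0.5
  yb <- abs(grid$y_centers) > 1.7 & abs(grid$y_centers) < 2.3
  yc <- abs(grid$y_centers) < 0.5
  li <- match(l_fill, luminance)
  for (ti in seq_along(time)) {
    m <- matrix(0, nx, ny)
    m[xb, yc] <- ev[ti]
    m[xc, yb] <- eh[ti]
    m[xc, yc] <- sv[ti]
    vals[, , li, ti] <- m
  }
  response_tensor(vals, grid, luminance, time)
}

## Simple separable population design: site patterns differ by luminance so a
## linear decoder can order black < gray < white; optional Gaussian noise.
make_separable_design <- function(n_sites = 8, n_trials = 12, noise = 0,
                                  seed = 1) {
  lums <- rep(c(-1, 0, 1), each = 2 * n_trials)
  locs <- rep(rep(c("surface", "edge"), each = n_trials), 3)
  m <- length(lums)
  with_seed(seed, {
    pattern <- matrix(rnorm(3 * n_sites), 3, n_sites)
    X <- pattern[lums + 2, , drop = FALSE] + matrix(rnorm(m * n_sites, 0, noise), m, n_sites)
    structure(list(x = X, luminance = lums, location = locs,
                   n_trials = n_trials, noise_sd = noise),
              class = "population_design")
  })
}

## Small, fast input tensor + ground-truth regime reused across tests.
tiny_input_params <- input_layer_params()
tiny_input <- generate_input_layer_tensor(tiny_input_params)
tiny_gt <- default_ground_truth(tiny_input_params)
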