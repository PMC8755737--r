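test_that("spatial pooling applies Gaussian weights to site positions", {
  r <- matrix(1, 1, 5)
  expect_equal(spatial_pool(r, positions = 0, center = 0, sigma = 0.5),
               rep(1, 5))
  r2 <- matrix(1, 2, 5)
  pooled <- spatial_pool(r2, positions = c(-0.5, 0.5), center = 0, sigma = 0.5)
  expect_equal(pooled, rep(2 * exp(-1 / 2), 5))
  ## vanishing sigma keeps only the co-located site
  r3 <- matrix(c(1, 5), 2, 4)
  expect_equal(spatial_pool(r3, c(0, 1), 0, sigma = 1e-4), rep(1, 4))
  expect_error(spatial_pool(matrix(0, 0, 3), numeric(0), 0, 1), "empty")
})

test_that("temporal transfer preserves DC, is the identity for a delta kernel", {
  kp_delta <- kernel_params(delay = log(1), sigma = 1e-3)
  x <- sin(seq(0, 6, length.out = 300))
  expect_equal(temporal_transfer(x, kp_delta), x, tolerance = 1e-12)

  kp <- kernel_params(delay = log(20), sigma = 0.5)
  const <- rep(3, 400)
  out <- temporal_transfer(const, kp)
  expect_equal(out[300:400], rep(3, 101), tolerance = 1e-9)

  k <- temporal_kernel(kp)
  expect_equal(sum(k), 1)
  expect_equal(which.max(k), 20)   # mode at t = exp(delay)
})

test_that("forward models are linear and reduce/cancel exactly", {
  prof <- profile_along_x(tiny_input, 1)
  pos <- attr(prof, "positions")
  oc <- c("surface", "edge")
  p0 <- transmission_params(w_i = 0)
  a <- forward_model_a(prof, pos, c(0, 2), oc, p0)
  b <- forward_model_b(prof, pos, c(0, 2), oc, p0)
  expect_identical(a, b)

  p2 <- transmission_params(w_i = 0.8)
  expect_equal(forward_model_a(2 * prof, pos, c(0, 2), oc, p2),
               2 * forward_model_a(prof, pos, c(0, 2), oc, p2))
  zero <- transmission_params(w_e_surface = 0, w_e_edge = 0, w_i = 0)
  expect_true(all(forward_model_a(prof, pos, c(0, 2), oc, zero) == 0))

  ## identical pathways with equal gains cancel exactly
  kp <- kernel_params(log(8), 0.4)
  pc <- transmission_params(sigma_e = 0.5, sigma_i = 0.5, w_e_surface = 0.7,
                            w_e_edge = 0.7, w_i = 0.7,
                            kernel_e = kp, kernel_i = kp)
  expect_equal(forward_model_b(prof, pos, c(0, 2), oc, pc),
               matrix(0, 2, ncol(prof)), tolerance = 1e-12)
})

test_that("nonlocal inhibition with localized edge input drives interiors negative", {
  tmv <- default_time
  edge_in <- matrix(0, 35, length(tmv))
  xs <- default_grid$x_centers
  wave <- ifelse(tmv > 30, 1, 0)
  edge_in[abs(xs) > 1.7 & abs(xs) < 2.3, ] <- rep(wave, each = 6)
  p <- transmission_params(sigma_e = 0.1, sigma_i = 1.5, w_i = 1)
  out <- forward_model_b(edge_in, xs, c(0, 2), c("surface", "edge"), p)
  expect_lt(min(out[1, ]), 0)                      # interior inhibited
  s_in <- se_ratio(rep(0, length(tmv)), wave, tmv)  # input has no surface drive
  expect_equal(s_in, 0)
})

test_that("model-B output reduces the surface/edge ratio relative to its input", {
  tmv <- tiny_input$time
  out_b <- generate_output_layer_tensor(tiny_input, tiny_gt$model_params, "B")
  se_of <- function(tn) {
    e <- baseline_subtract(as.numeric(extract_edge_response(tn, 1)), tmv)
    s <- baseline_subtract(extract_surface_response(tn, 1), tmv)
    se_ratio(s, e, tmv, c(40, 100))
  }
  expect_lt(se_of(out_b), se_of(tiny_input))
})

test_that("goodness of fit matches the closed-form cases", {
  x <- c(0, 1, 2, 1, 0)
  expect_equal(goodness_of_fit(x, x, pn = 1), 1)
  expect_equal(goodness_of_fit(x, rep(mean(x), 5), pn = 1), -1)
  set.seed(3)
  a <- rnorm(50); b <- a + rnorm(50, 0, 0.2)
  g1 <- goodness_of_fit(a, b, pn = 3)
  expect_equal(goodness_of_fit(7 * a, 7 * b, pn = 3), g1)
  expect_lte(g1, 1)
  expect_true(is.na(goodness_of_fit(rep(1, 5), rep(1, 5), pn = 1)))
})

test_that("noiseless self-generated model-A data are recovered nearly perfectly", {
  prof <- profile_along_x(tiny_input, 1)
  pos <- attr(prof, "positions")
  truth <- transmission_params(sigma_e = 0.45, w_e_surface = 0.8,
                               w_e_edge = 1.3, w_i = 0,
                               kernel_e = kernel_params(log(6), 0.35))
  tgt <- forward_model_a(prof, pos, c(0, 2), c("surface", "edge"), truth)
  fit <- fit_model(prof, pos, tgt[1, ], tgt[2, ], model = "A",
                   n_starts = 4, seed = 2,
                   init = list(sigma_e = 0.5, delay_e = log(5)))
  expect_gte(fit$gof, 0.999)
  expect_equal(fit$params$sigma_e, 0.45, tolerance = 0.01)
  expect_equal(fit$params$w_e_edge / fit$params$w_e_surface, 1.3 / 0.8,
               tolerance = 0.01)
  expect_equal(exp(fit$params$kernel_e$delay), 6, tolerance = 0.02)
  ## objective at the truth is no better than the fitted optimum (+ tolerance)
  obj <- function(p) mean((forward_model_a(prof, pos, c(0, 2),
                                           c("surface", "edge"), p) - tgt)^2)
  expect_lte(fit$objective, obj(truth) + 1e-10)
})

test_that("single-point inhibition scans return the constrained fit", {
  prof <- profile_along_x(tiny_input, 1)
  pos <- attr(prof, "positions")
  truth <- transmission_params(sigma_e = 0.4, sigma_i = 0.8, w_i = 1)
  tgt <- forward_model_b(prof, pos, c(0, 2), c("surface", "edge"), truth)
  scan <- inhibition_range_scan(prof, pos, tgt[1, ], tgt[2, ],
                                sigma_i_grid = 0.8, n_starts = 2, seed = 3)
  expect_equal(nrow(scan), 1L)
  expect_equal(attr(scan, "best"), 0.8)
  expect_gt(scan$gof, 0.99)
})

test_that("I/E ratio is zero without inhibition and one at exact cancellation", {
  prof <- profile_along_x(tiny_input, 1)
  pos <- attr(prof, "positions")
  expect_equal(ie_ratio(transmission_params(w_i = 0), prof, pos), 0)
  kp <- kernel_params(log(8), 0.4)
  pc <- transmission_params(sigma_e = 0.5, sigma_i = 0.5, w_e_surface = 0.7,
                            w_e_edge = 0.7, w_i = 0.7,
                            kernel_e = kp, kernel_i = kp)
  expect_equal(as.numeric(ie_ratio(pc, prof, pos)), 1, tolerance = 1e-10)
  expect_true(is.na(ie_ratio(transmission_params(w_e_surface = 0), prof, pos)))
})

test_that("inhibitory-gain calibration hits the requested I/E exactly", {
  prof <- profile_along_x(tiny_input, 1)
  pos <- attr(prof, "positions")
  p <- calibrate_wi(transmission_params(), prof, pos, target_ie = 0.74)
  expect_equal(as.numeric(ie_ratio(p, prof, pos)), 0.74, tolerance = 1e-10)
  pe <- calibrate_wi(p, prof, pos, target_ie = 0.37, out_position = 2,
                     out_class = "edge")
  expect_equal(as.numeric(ie_ratio(pe, prof, pos, out_position = 2,
                                   out_class = "edge")), 0.37,
               tolerance = 1e-10)
})
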