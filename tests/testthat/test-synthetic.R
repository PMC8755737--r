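test_that("input-layer tensor honors latency, amplitudes and black dominance", {
  ip <- input_layer_params()
  tn <- tiny_input
  tm <- tn$time
  ## silent before onset latency
  pre <- tn$values[, , , tm <= ip$onset_latency]
  expect_true(all(pre == 0))
  ## gray condition is a blank
  expect_true(all(tn$values[, , 2, ] == 0))
  ## region-summed amplitudes: extracted peaks equal the parameters
  expect_equal(max(extract_surface_response(tn, 1)), ip$surface_amplitude)
  expect_equal(max(as.numeric(extract_edge_response(tn, 1))), ip$edge_amplitude)
  ## black = white x black_dominance, exactly
  expect_equal(tn$values[, , 1, ], ip$black_dominance * tn$values[, , 3, ])
})

test_that("equal generator amplitudes give a surface/edge ratio of exactly 1", {
  ip <- input_layer_params(surface_amplitude = 0.8, edge_amplitude = 0.8,
                           adaptation_fraction = c(0.3, 0.3))
  tn <- generate_input_layer_tensor(ip)
  tm <- tn$time
  s <- baseline_subtract(extract_surface_response(tn, 1), tm)
  e <- baseline_subtract(as.numeric(extract_edge_response(tn, 1)), tm)
  expect_equal(se_ratio(s, e, tm, c(40, 100)), 1)
  expect_equal(se_ratio(s, e, tm, c(120, 180)), 1)
})

test_that("zero amplitudes yield a null tensor and flagged downstream metrics", {
  ip <- input_layer_params(surface_amplitude = 0, edge_amplitude = 0)
  tn <- generate_input_layer_tensor(ip)
  expect_true(all(tn$values == 0))
  expect_warning(np <- normalize_profile(
    as.numeric(extract_edge_response(tn, 1)), extract_surface_response(tn, 1)))
  expect_true(all(is.na(np$r_edge)))
})

test_that("a sustained plateau has a sustain index at the flat-response value", {
  ip <- input_layer_params(adaptation_fraction = c(0, 0), rise_time = 0.5)
  tn <- generate_input_layer_tensor(ip)
  s <- baseline_subtract(extract_surface_response(tn, 1), tn$time)
  expect_equal(as.numeric(sustain_index(s, tn$time)), 0.5, tolerance = 5e-3)
})

test_that("the zero-inhibition output reduction is bit-compatible with model A", {
  p0 <- transmission_params(sigma_e = 0.35, w_i = 0)
  out_b <- generate_output_layer_tensor(tiny_input, p0, model = "B")
  out_a <- generate_output_layer_tensor(tiny_input, p0, model = "A")
  expect_identical(out_b$values, out_a$values)
  ## the y = 0 row is exactly the 1-D forward pass along x
  xs <- tiny_input$grid$x_centers
  y0 <- which.min(abs(tiny_input$grid$y_centers))
  prof <- tiny_input$values[, y0, 3, ]
  direct <- forward_model_a(prof, xs, xs, position_class_1d(xs, 0), p0)
  expect_identical(out_b$values[, y0, 3, ], direct)
})

test_that("trial populations are deterministic, unbiased and noise-scaled", {
  tn <- tiny_input
  d1 <- generate_trial_population(tn, n_sites = 8, n_trials = 10,
                                  noise_sd = 0.2, seed = 5)
  d2 <- generate_trial_population(tn, n_sites = 8, n_trials = 10,
                                  noise_sd = 0.2, seed = 5)
  expect_identical(d1$x, d2$x)
  d3 <- generate_trial_population(tn, n_sites = 8, n_trials = 10,
                                  noise_sd = 0.2, seed = 6)
  expect_false(identical(d1$x, d3$x))

  ## noiseless: every trial equals its condition mean
  d0 <- generate_trial_population(tn, n_sites = 5, n_trials = 6,
                                  noise_sd = 0, seed = 2)
  cell <- interaction(d0$luminance, d0$location)
  for (s in seq_len(ncol(d0$x))) {
    spread <- tapply(d0$x[, s], cell, function(v) diff(range(v)))
    expect_true(all(spread == 0))
  }

  ## mean recovery: empirical condition means within 3 standard errors
  dn <- generate_trial_population(tn, n_sites = 4, n_trials = 400,
                                  noise_sd = 0.2, seed = 9)
  mu <- generate_trial_population(tn, n_sites = 4, n_trials = 2,
                                  noise_sd = 0, seed = 9)
  cell_n <- interaction(dn$luminance, dn$location)
  cell_m <- interaction(mu$luminance, mu$location)
  for (s in seq_len(4)) {
    em <- tapply(dn$x[, s], cell_n, mean)
    tm_ <- tapply(mu$x[, s], cell_m, mean)
    se <- tapply(dn$x[, s], cell_n, function(v) stats::sd(v) / sqrt(length(v)))
    expect_true(all(abs(em - tm_) <= 3 * pmax(se, 1e-12)))
  }

  expect_error(generate_trial_population(list(tn), n_sites = 2, n_trials = 5,
                                         seed = 1),
               "exceeds")
})

test_that("reverse-correlation datasets separate surface and edge drive", {
  rc <- generate_reverse_correlation_dataset(tiny_input_params,
                                             tiny_gt$model_params)
  tm <- rc$square$input$time
  ## frame interior is exactly zero (input level)
  expect_true(all(extract_surface_response(rc$frame$input, 1) == 0))
  expect_true(all(extract_surface_response(rc$frame$input, -1) == 0))
  ## square and frame edges carry identical input drive: suppression 0 exactly
  e_sq_in <- baseline_subtract(as.numeric(extract_edge_response(rc$square$input, 1)), tm)
  e_fr_in <- baseline_subtract(as.numeric(extract_edge_response(rc$frame$input, 1)), tm)
  expect_equal(edge_suppression_index(e_fr_in, e_sq_in, tm), 0)
  ## with inhibition off and tight excitatory pooling, the transformed edges
  ## stay equal up to the residual surface drive leaking into the pool
  p0 <- transmission_params(sigma_e = 0.05, w_i = 0)
  rc0 <- generate_reverse_correlation_dataset(tiny_input_params, p0)
  e_sq <- baseline_subtract(as.numeric(extract_edge_response(rc0$square$output, 1)), tm)
  e_fr <- baseline_subtract(as.numeric(extract_edge_response(rc0$frame$output, 1)), tm)
  expect_equal(edge_suppression_index(e_fr, e_sq, tm), 0, tolerance = 1e-3)
  ## with surface-driven inhibition, the square edge is weaker than the frame edge
  e_sq_b <- baseline_subtract(as.numeric(extract_edge_response(rc$square$output, 1)), tm)
  e_fr_b <- baseline_subtract(as.numeric(extract_edge_response(rc$frame$output, 1)), tm)
  expect_gt(edge_suppression_index(e_fr_b, e_sq_b, tm), 0)
  ## pulsed surface response is biphasic: clear suppression lobe
  s_b <- baseline_subtract(extract_surface_response(rc$square$output, 1), tm)
  expect_gt(surface_suppression_index(s_b, tm), 0.2)
})

test_that("the default ground truth carries its calibration", {
  gt <- tiny_gt
  prof <- profile_along_x(gt$input_tensor, 1)
  pos <- attr(prof, "positions")
  expect_equal(as.numeric(ie_ratio(gt$model_params$white, prof, pos)), 1.1,
               tolerance = 1e-8)
  prof_b <- profile_along_x(gt$input_tensor, -1)
  expect_equal(as.numeric(ie_ratio(gt$model_params$black, prof_b, pos)), 0.74,
               tolerance = 1e-8)
  expect_equal(gt$model_params$white$sigma_i / gt$model_params$white$sigma_e, 2)
})
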