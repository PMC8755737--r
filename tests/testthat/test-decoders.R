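test_that("lambda grid is 20 log-spaced values from 0.001 to 40", {
  g <- lambda_grid()
  expect_length(g, 20L)
  expect_equal(g[1], 0.001)
  expect_equal(g[20], 40)
  ratios <- g[-1] / g[-20]
  expect_equal(ratios, rep((40 / 0.001)^(1 / 19), 19))
})

test_that("stratified split respects fractions, disjointness and cell coverage", {
  d <- make_separable_design(n_sites = 4, n_trials = 20)
  sp <- stratified_split(d, seed = 3)
  idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(idx), seq_len(nrow(d$x)))
  expect_equal(length(sp$train), 0.60 * nrow(d$x))
  expect_equal(length(sp$validation), 0.15 * nrow(d$x))
  cell <- interaction(d$luminance, d$location)
  for (part in sp) expect_true(all(table(cell[part]) >= 1))
  ## deterministic given the seed
  expect_identical(sp, stratified_split(d, seed = 3))
  expect_false(identical(sp$train, stratified_split(d, seed = 4)$train))
})

test_that("test split never touches fitting (data-poisoning check)", {
  d <- make_separable_design(n_sites = 6, n_trials = 16, noise = 0.3)
  dec1 <- fit_luminance_decoder(d, lambda = 0.7, seed = 5)
  d2 <- d
  d2$x[dec1$split$test, ] <- 1e6 * matrix(rnorm(length(dec1$split$test) * 6),
                                          ncol = 6)
  dec2 <- fit_luminance_decoder(d2, lambda = 0.7, seed = 5)
  expect_identical(dec1$w, dec2$w)
  expect_identical(dec1$w0, dec2$w0)
  sel1 <- select_lambda(d, seed = 5)
  sel2 <- select_lambda(d2, seed = 5)
  expect_identical(sel1$lambda, sel2$lambda)
})

test_that("rank accuracy scores orderings with ties incorrect", {
  pred <- c(rep(-5, 10), rep(0, 10), rep(5, 10))
  lab <- rep(c(-1, 0, 1), each = 10)
  expect_equal(rank_accuracy(pred, lab, 500, seed = 1), 100)
  expect_equal(rank_accuracy(-pred, lab, 500, seed = 1), 0)
  expect_equal(rank_accuracy(rep(1, 30), lab, 500, seed = 1), 0)  # all tied
  expect_error(rank_accuracy(pred[1:20], lab[1:20], 500, 1), "condition")

  ## identical continuous distributions: all 6 orderings equiprobable
  set.seed(8)
  pred_same <- rnorm(600)
  lab_same <- rep(c(-1, 0, 1), 200)
  acc <- rank_accuracy(pred_same, lab_same, 5000, seed = 2)
  expect_gt(acc, 100 / 6 - 3.5)
  expect_lt(acc, 100 / 6 + 3.5)
})

test_that("lambda selection finds the grid ends appropriate to the signal", {
  informative <- make_separable_design(n_sites = 6, n_trials = 16, noise = 0.05,
                                       seed = 2)
  noise_only <- make_separable_design(n_sites = 6, n_trials = 16, seed = 2)
  noise_only$x <- matrix(rnorm(length(noise_only$x)), nrow(noise_only$x))
  li <- select_lambda(informative, seed = 1)$lambda
  ln <- select_lambda(noise_only, seed = 1)$lambda
  expect_lt(li, 0.1)
  expect_gt(ln, li)
  f <- fit_luminance_decoder(noise_only, lambda = ln, seed = 1)
  expect_lt(sum(abs(f$w)), 0.5)
})

test_that("noiseless separable designs decode at ceiling, permuted at chance", {
  d <- make_separable_design(n_sites = 8, n_trials = 12, noise = 0)
  res <- decode_luminance(d, lambda = 0.001, seed = 1)
  expect_equal(res$accuracy, 100)

  set.seed(9)
  accs <- vapply(1:5, function(k) {
    dp <- make_separable_design(n_sites = 8, n_trials = 20, noise = 0.2,
                                seed = 30 + k)
    dp$luminance <- sample(dp$luminance)
    decode_luminance(dp, lambda = 0.001, seed = k)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 6), 6)
})

test_that("time-resolved accuracy is at chance before onset and high after", {
  tn <- tiny_gt$input_tensor
  d <- generate_trial_population(tn, n_sites = 24, n_trials = 60,
                                 noise_sd = 0.15, seed = 6,
                                 time_bins = seq(-50, 250, by = 50))
  sub <- design_subset(d, location = "surface")
  dec <- fit_luminance_decoder(sub, lambda = 0.1, seed = 2)
  tr <- time_resolved_accuracy(sub, dec, n_boot = 1000, seed = 3)
  expect_equal(nrow(tr), 6L)
  ## pre-stimulus bin: no signal, so accuracy sits at chance up to the
  ## finite-test-set spread of the triple-ordering probability
  pre <- tr$accuracy[tr$bin_center < 0]
  expect_lt(abs(pre - 100 / 6), 15)
  expect_gt(max(tr$accuracy[tr$bin_center > 50]), 80)
  expect_lt(pre, min(tr$accuracy[tr$bin_center > 50]))
})

test_that("population-size curve has zero sem at full size and rises with size", {
  d <- make_separable_design(n_sites = 12, n_trials = 12, noise = 1.5, seed = 3)
  curve <- population_size_curve(d, sizes = c(2, 6, 12), n_populations = 20,
                                 lambda = 0.1, seed = 4, n_boot = 400)
  expect_equal(curve$sem[curve$size == 12], 0)
  expect_true(all(diff(curve$mean_accuracy) > -curve$sem[-nrow(curve)] - 1e-9))
  expect_error(population_size_curve(d, sizes = 13), "exceeds")
})

test_that("location decoder separates classes and degrades to the prior", {
  d <- make_separable_design(n_sites = 6, n_trials = 16, noise = 0.1, seed = 5)
  ## make locations differ: edge trials shifted in mean
  d$x <- d$x + 2 * (d$location == "edge")
  dec <- fit_location_decoder(d, lambda = 0.001, seed = 1)
  expect_equal(dec$accuracy, 100)

  dshuf <- d
  with_seed(42, dshuf$location <- sample(dshuf$location))
  accs <- fit_location_decoder(dshuf, lambda = 0.001, seed = 1)$accuracy
  expect_lt(abs(accs - 50), 25)

  dec_inf <- fit_location_decoder(d, lambda = 1e7, seed = 1)
  expect_equal(dec_inf$w, rep(0, 6))
})

test_that("multiplexed decoding composes location and luminance stages", {
  d <- make_separable_design(n_sites = 6, n_trials = 20, noise = 0.1, seed = 6)
  d$x <- d$x + 3 * (d$location == "edge")
  mx <- multiplexed_decode(d, lambda_location = 0.001, lambda_luminance = 0.001,
                           seed = 2, n_boot = 400)
  expect_equal(mx$location_accuracy, 100)
  expect_false(mx$luminance_by_group$surface$empty)
  expect_false(mx$luminance_by_group$edge$empty)
  expect_gt(mx$luminance_by_group$surface$accuracy, 90)
  expect_gt(mx$luminance_by_group$edge$accuracy, 90)

  ## uninformative design with full shrinkage: constant p = 0.5 predicts
  ## everything as edge, leaving the surface group empty and flagged
  dn <- make_separable_design(n_sites = 4, n_trials = 12, seed = 7)
  dn$x <- matrix(rnorm(length(dn$x)), nrow(dn$x))
  mxn <- multiplexed_decode(dn, lambda_location = 1e7, lambda_luminance = 0.001,
                            seed = 2, n_boot = 200)
  expect_true(mxn$luminance_by_group$surface$empty ||
              mxn$luminance_by_group$edge$empty)
})

test_that("decoding is deterministic given the seed", {
  d <- make_separable_design(n_sites = 6, n_trials = 12, noise = 0.4, seed = 9)
  r1 <- decode_luminance(d, lambda = 0.7, seed = 11)
  r2 <- decode_luminance(d, lambda = 0.7, seed = 11)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$decoder$w, r2$decoder$w)
})
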