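#' Log-spaced regularization grid
#'
#' Twenty lambda values equally spaced logarithmically between 0.001 and 40.
#'
#' @param from,to,length grid limits and size.
#' @export
lambda_grid <- function(from = 0.001, to = 40, length = 20L) {
  exp(seq(log(from), log(to), length.out = length))
}

## Stratified 60/15/25 split by (luminance x location) cell, seeded.
## Guarantees at least one trial per cell in every split when the cell has
## >= 3 trials.
stratified_split <- function(design, fractions = c(0.60, 0.15, 0.25), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  cell <- interaction(design$luminance, design$location, drop = TRUE)
  train <- integer(0); val <- integer(0); test <- integer(0)
  with_seed(seed, {
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      n <- length(idx)
      if (n < 3L) stop("each (luminance x location) cell needs >= 3 trials to split")
      idx <- sample(idx)
      n_tr <- max(1L, round(fractions[1] * n))
      n_va <- max(1L, round(fractions[2] * n))
      if (n_tr + n_va >= n) { n_tr <- n - 2L; n_va <- 1L }
      train <- c(train, idx[seq_len(n_tr)])
      val <- c(val, idx[n_tr + seq_len(n_va)])
      test <- c(test, idx[(n_tr + n_va + 1L):n])
    }
  })
  list(train = sort(train), validation = sort(val), test = sort(test))
}

## Per-site normalization scale: maximum absolute trial-averaged condition
## mean, computed from the given trials only (training split, to keep the
## test split out of all fitting decisions). Zero-max sites get scale NA.
site_scales <- function(X, luminance, location) {
  cell <- interaction(luminance, location, drop = TRUE)
  scales <- apply(X, 2, function(col) {
    mx <- max(abs(tapply(col, cell, mean)))
    if (mx == 0) NA_real_ else mx
  })
  if (anyNA(scales))
    warning(sprintf("%d zero-response site(s) excluded from decoding", sum(is.na(scales))))
  scales
}

apply_scales <- function(X, scales) {
  keep <- which(!is.na(scales))
  sweep(X[, keep, drop = FALSE], 2, scales[keep], "/")
}

#' Fit the L1-regularized linear luminance decoder
#'
#' Splits the design 60/15/25 (train/validation/test, stratified by
#' luminance x location), normalizes each site by its maximum trial-averaged
#' response on the training split, and fits the linear decoder
#' `L = X W + w0` by minimizing `(1/m) sum (Y - L)^2 + (lambda/m)|W|_1`
#' (coordinate descent) on the training split only.
#'
#' @param design a `population_design` (see
#'   [generate_trial_population()]).
#' @param lambda regularization strength; `"auto"` selects it on the
#'   validation split via [select_lambda()]. The canonical fixed value is
#'   0.7.
#' @param seed integer seed (controls the split).
#' @param fractions split fractions.
#' @return object of class `luminance_decoder`: `w`, `w0`, `lambda`,
#'   `scales`, `split`, `test_predictions`, `test_luminance`, `fit`
#'   diagnostics.
#' @export
fit_luminance_decoder <- function(design, lambda = 0.7, seed = 1,
                                  fractions = c(0.60, 0.15, 0.25)) {
  sp <- stratified_split(design, fractions, seed)
  if (length(unique(design$luminance[sp$train])) < 2L)
    stop("training split must contain at least 2 luminance conditions")
  scales <- site_scales(design$x[sp$train, , drop = FALSE],
                        design$luminance[sp$train], design$location[sp$train])
  Xtr <- apply_scales(design$x[sp$train, , drop = FALSE], scales)
  ytr <- design$luminance[sp$train]
  if (identical(lambda, "auto")) {
    lambda <- select_lambda(design, seed = seed, fractions = fractions)$lambda
  }
  fit <- lasso_cd(Xtr, ytr, lambda)
  if (!fit$converged) stop("lasso coordinate descent did not converge")
  Xte <- apply_scales(design$x[sp$test, , drop = FALSE], scales)
  dec <- structure(
    list(w = fit$w, w0 = fit$w0, lambda = lambda, scales = scales,
         split = sp, fit = fit,
         test_predictions = drop(Xte %*% fit$w) + fit$w0,
         test_luminance = design$luminance[sp$test]),
    class = "luminance_decoder"
  )
  dec
}

#' Predict luminance for new response rows
#'
#' @param object a `luminance_decoder`.
#' @param newdata `trials x sites` matrix on the raw response scale.
#' @param ... unused.
#' @export
predict.luminance_decoder <- function(object, newdata, ...) {
  drop(apply_scales(as.matrix(newdata), object$scales) %*% object$w) + object$w0
}

#' Select the regularization strength on the validation split
#'
#' Fits the luminance decoder on the training split for every lambda on the
#' grid and returns the lambda with the lowest validation MSE. Ties go to
#' the smaller lambda.
#'
#' @inheritParams fit_luminance_decoder
#' @param grid candidate lambdas (default [lambda_grid()]).
#' @return list with `lambda`, `mse` (per grid point), `grid`.
#' @export
select_lambda <- function(design, grid = lambda_grid(), seed = 1,
                          fractions = c(0.60, 0.15, 0.25)) {
  sp <- stratified_split(design, fractions, seed)
  scales <- site_scales(design$x[sp$train, , drop = FALSE],
                        design$luminance[sp$train], design$location[sp$train])
  Xtr <- apply_scales(design$x[sp$train, , drop = FALSE], scales)
  ytr <- design$luminance[sp$train]
  Xva <- apply_scales(design$x[sp$validation, , drop = FALSE], scales)
  yva <- design$luminance[sp$validation]
  mse <- vapply(grid, function(lam) {
    f <- lasso_cd(Xtr, ytr, lam)
    mean((yva - (drop(Xva %*% f$w) + f$w0))^2)
  }, numeric(1))
  list(lambda = grid[which.min(mse)], mse = mse, grid = grid)
}

#' Bootstrap rank-order accuracy of luminance predictions
#'
#' Repeatedly samples one predicted luminance from each stimulus condition
#' (black, gray, white) and scores the triple correct when the predictions
#' order as black < gray < white (strictly; exact ties count as incorrect).
#'
#' @param predictions numeric predicted luminances.
#' @param luminance true labels in `{-1, 0, 1}`, same length.
#' @param n_boot bootstrap triples (default 1000).
#' @param seed integer seed.
#' @return accuracy in percent (0-100).
#' @export
rank_accuracy <- function(predictions, luminance, n_boot = 1000L, seed = 1) {
  pb <- predictions[luminance == -1]
  pg <- predictions[luminance == 0]
  pw <- predictions[luminance == 1]
  if (length(pb) == 0L || length(pg) == 0L || length(pw) == 0L)
    stop("every luminance condition needs at least one prediction")
  with_seed(seed, {
    b <- sample(pb, n_boot, replace = TRUE)
    g <- sample(pg, n_boot, replace = TRUE)
    w <- sample(pw, n_boot, replace = TRUE)
    100 * mean(b < g & g < w)
  })
}

#' Full luminance-decoding pipeline on one design
#'
#' Convenience wrapper: fit (or select lambda for) the decoder and report
#' the bootstrap rank accuracy of its test-split predictions.
#'
#' @inheritParams fit_luminance_decoder
#' @param n_boot bootstrap triples.
#' @return list with `decoder`, `accuracy` (percent), `n_boot`.
#' @export
decode_luminance <- function(design, lambda = 0.7, seed = 1, n_boot = 1000L) {
  dec <- fit_luminance_decoder(design, lambda, seed)
  acc <- rank_accuracy(dec$test_predictions, dec$test_luminance, n_boot,
                       seed = derive_seeds(seed, 1))
  list(decoder = dec, accuracy = acc, n_boot = n_boot)
}

#' Time-resolved decoding accuracy
#'
#' Applies a decoder trained on the 40-250 ms window to responses averaged
#' in serial 50-ms bins (the design must carry `x_time`), returning one
#' rank accuracy per bin on the decoder's test split. Bins with no data are
#' dropped with a warning.
#'
#' @param design a `population_design` built with `time_bins`.
#' @param decoder a fitted `luminance_decoder` on the same design.
#' @param n_boot,seed bootstrap settings.
#' @return `data.frame` with `bin_center`, `accuracy`.
#' @export
time_resolved_accuracy <- function(design, decoder, n_boot = 1000L, seed = 1) {
  if (is.null(design$x_time)) stop("design has no time-resolved responses (x_time)")
  te <- decoder$split$test
  nb <- dim(design$x_time)[3]
  seeds <- derive_seeds(seed, nb)
  rows <- lapply(seq_len(nb), function(bi) {
    Xb <- design$x_time[te, , bi]
    if (anyNA(Xb)) { warning(sprintf("dropping incomplete bin %d", bi)); return(NULL) }
    pred <- drop(apply_scales(Xb, decoder$scales) %*% decoder$w) + decoder$w0
    data.frame(bin_center = design$bin_centers[bi],
               accuracy = rank_accuracy(pred, design$luminance[te],
                                        n_boot, seeds[bi]))
  })
  do.call(rbind, rows)
}

#' Decoding accuracy as a function of population size
#'
#' For each requested size, resamples that many sites without replacement
#' `n_populations` times, refits the luminance decoder on each resampled
#' population and records its rank accuracy. Sub-populations differ only in
#' the sampled sites; the split and bootstrap streams are shared, so at
#' size `N` all populations are identical and the s.e.m. is zero.
#'
#' @param design a `population_design`.
#' @param sizes vector of population sizes, all `<= ncol(design$x)`.
#' @param n_populations resampled populations per size (default 100).
#' @param lambda decoder regularization.
#' @param seed master seed.
#' @param n_boot bootstrap triples per accuracy.
#' @return `data.frame` with `size`, `mean_accuracy`, `sem`, plus the
#'   attribute `accuracies` (size x population matrix).
#' @export
population_size_curve <- function(design, sizes, n_populations = 100L,
                                  lambda = 0.7, seed = 1, n_boot = 1000L) {
  N <- ncol(design$x)
  if (any(sizes > N)) stop("requested population size exceeds available sites")
  seeds <- derive_seeds(seed, length(sizes) * n_populations)
  fit_seed <- derive_seeds(seed + 1, 2)
  acc <- matrix(NA_real_, length(sizes), n_populations)
  k <- 0L
  for (si in seq_along(sizes)) {
    for (p in seq_len(n_populations)) {
      k <- k + 1L
      keep <- with_seed(seeds[k], sample.int(N, sizes[si]))
      sub <- design
      sub$x <- design$x[, keep, drop = FALSE]
      sub$x_time <- NULL
      dec <- fit_luminance_decoder(sub, lambda, seed = fit_seed[1])
      acc[si, p] <- rank_accuracy(dec$test_predictions, dec$test_luminance,
                                  n_boot, seed = fit_seed[2])
    }
  }
  out <- data.frame(
    size = sizes,
    mean_accuracy = rowMeans(acc),
    sem = apply(acc, 1, function(a) stats::sd(a) / sqrt(length(a)))
  )
  attr(out, "accuracies") <- acc
  out
}

#' Fit the L1-regularized logistic location decoder
#'
#' Decodes whether a population response was driven by the stimulus edge or
#' surface: `P(edge | X) = 1 / (1 + exp(-(X W + w0)))`, fit by minimizing
#' the penalized cross-entropy with an `lambda/(2m) |W|_1` term on the
#' training split. Classification rule: `p >= 0.5` predicts edge. Gray
#' (blank) trials carry no location signal and are excluded.
#'
#' @inheritParams fit_luminance_decoder
#' @param lambda regularization strength; canonical fixed value 0.1.
#' @return object of class `location_decoder` with `w`, `w0`, `lambda`,
#'   `scales`, `split`, `test_probabilities`, `test_location`, `accuracy`
#'   (percent correct on the test split).
#' @export
fit_location_decoder <- function(design, lambda = 0.1, seed = 1,
                                 fractions = c(0.60, 0.15, 0.25)) {
  design <- design_subset(design, luminance = c(-1, 1))
  if (length(unique(design$location)) < 2L)
    stop("both location classes (edge, surface) required")
  sp <- stratified_split(design, fractions, seed)
  scales <- site_scales(design$x[sp$train, , drop = FALSE],
                        design$luminance[sp$train], design$location[sp$train])
  Xtr <- apply_scales(design$x[sp$train, , drop = FALSE], scales)
  ytr <- as.integer(design$location[sp$train] == "edge")
  fit <- logistic_lasso(Xtr, ytr, lambda)
  Xte <- apply_scales(design$x[sp$test, , drop = FALSE], scales)
  p <- 1 / (1 + exp(-(drop(Xte %*% fit$w) + fit$w0)))
  truth <- as.integer(design$location[sp$test] == "edge")
  structure(
    list(w = fit$w, w0 = fit$w0, lambda = lambda, scales = scales,
         split = sp, fit = fit,
         test_probabilities = p, test_location = design$location[sp$test],
         accuracy = 100 * mean((p >= 0.5) == truth)),
    class = "location_decoder"
  )
}

#' Multiplexed location-then-luminance decoding
#'
#' Decodes stimulus location first, then luminance within each
#' predicted-location group using a group-specific luminance decoder fit on
#' that location's training trials. A predicted group left empty is flagged
#' and its luminance stage skipped.
#'
#' @param design a `population_design`.
#' @param lambda_location,lambda_luminance regularization strengths.
#' @param seed master seed.
#' @param n_boot bootstrap triples for the rank accuracies.
#' @return list with `location` (decoder), `location_accuracy`, and
#'   per-group luminance results (`accuracy`, `n`, `empty`).
#' @export
multiplexed_decode <- function(design, lambda_location = 0.1,
                               lambda_luminance = 0.7, seed = 1,
                               n_boot = 1000L) {
  loc <- fit_location_decoder(design, lambda_location, seed)
  lum_dec <- lapply(c(surface = "surface", edge = "edge"), function(g) {
    fit_luminance_decoder(design_subset(design, location = g),
                          lambda_luminance, seed)
  })
  nb_design <- design_subset(design, luminance = c(-1, 1))
  te <- loc$split$test
  pred_loc <- ifelse(loc$test_probabilities >= 0.5, "edge", "surface")
  groups <- lapply(c(surface = "surface", edge = "edge"), function(g) {
    idx <- te[pred_loc == g]
    if (length(idx) == 0L)
      return(list(empty = TRUE, accuracy = NA_real_, n = 0L))
    pred <- predict(lum_dec[[g]], nb_design$x[idx, , drop = FALSE])
    truth <- nb_design$luminance[idx]
    acc <- if (all(c(-1, 1) %in% truth)) {
      ## gray trials are excluded from location decoding; score the two-class
      ## ordering black < white by the same bootstrap-triple machinery using
      ## the group decoder's gray predictions from its own test split
      gray <- lum_dec[[g]]$test_predictions[lum_dec[[g]]$test_luminance == 0]
      rank_accuracy(c(pred, gray), c(truth, rep(0, length(gray))),
                    n_boot, derive_seeds(seed, 1))
    } else NA_real_
    list(empty = FALSE, accuracy = acc, n = length(idx))
  })
  list(location = loc, location_accuracy = loc$accuracy,
       luminance_by_group = groups)
}
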