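#' Configuration of the coding-strategy experiment
#'
#' @param n_populations resampled populations (default 50).
#' @param sites_per_decoder sites per decoder (default 32).
#' @param n_trials trials per (luminance x location) condition.
#' @param noise_fraction trial noise as a fraction of the reference peak
#'   response of the generating input dataset; the resulting absolute SD is
#'   shared by all condition sets so that signal changes, not noise
#'   rescaling, drive accuracy differences. The default of 0.5 matches the
#'   trial-to-trial variability of 210-ms windowed cortical MUA (coefficient
#'   of variation of order one half); much smaller values saturate every
#'   decoder at 100% and make the information redistribution invisible,
#'   much larger ones push even the edge readout off ceiling.
#' @param lambda decoder regularization (fixed inside the experiment).
#' @param n_boot bootstrap triples per accuracy.
#' @param seed master seed.
#' @export
strategy_config <- function(n_populations = 50L, sites_per_decoder = 32L,
                            n_trials = 50L, noise_fraction = 0.5,
                            lambda = 0.7, n_boot = 1000L, seed = 1L) {
  stopifnot(n_populations >= 1, sites_per_decoder >= 1, n_trials >= 2,
            noise_fraction >= 0)
  structure(
    list(n_populations = as.integer(n_populations),
         sites_per_decoder = as.integer(sites_per_decoder),
         n_trials = as.integer(n_trials), noise_fraction = noise_fraction,
         lambda = lambda, n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "strategy_config"
  )
}

## Reference peak: largest condition-mean response of the input tensor at the
## probed surface/edge bins, used to put all condition sets on one absolute
## noise scale.
reference_peak <- function(tensor, window = c(40, 250), edge_position = 2.0) {
  tm <- tensor$time
  wmask <- time_window(tm, window[1], window[2])
  x0 <- which.min(abs(tensor$grid$x_centers))
  xe <- which.min(abs(tensor$grid$x_centers - edge_position))
  y0 <- which.min(abs(tensor$grid$y_centers))
  vals <- c()
  for (l in tensor$luminance) {
    li <- lum_idx(tensor, l)
    vals <- c(vals, mean(tensor$values[x0, y0, li, wmask]),
              mean(tensor$values[xe, y0, li, wmask]))
  }
  max(abs(vals))
}

#' Run the coding-strategy experiment
#'
#' Simulates single-trial populations under three condition sets — the
#' input-layer response itself, its excitation-only (model A) transform, and
#' its excitation-plus-nonlocal-inhibition (model B) transform — fits
#' surface-based and edge-based luminance decoders on each population, and
#' quantifies how the transforms redistribute luminance information. The
#' population index is paired across condition sets (identical site gains
#' and noise draws), and trial noise uses a single absolute SD derived from
#' the input dataset.
#'
#' @param input_tensor input-layer [response_tensor()].
#' @param model_params transmission parameters (single set or
#'   `list(white, black)`), typically a fitted or ground-truth model B.
#' @param config a [strategy_config()].
#' @return object of class `strategy_result`: `accuracy` (array
#'   `condition_set x location x population`), `summary` (data.frame of
#'   mean +/- sem), and `tests` (paired comparisons: edge input vs model A,
#'   surface model A vs model B, edge model A vs model B).
#' @export
run_strategy_experiment <- function(input_tensor, model_params,
                                    config = strategy_config()) {
  out_a <- generate_output_layer_tensor(input_tensor, model_params, model = "A")
  out_b <- generate_output_layer_tensor(input_tensor, model_params, model = "B")
  sets <- list(input = input_tensor, model_a = out_a, model_b = out_b)
  noise_abs <- config$noise_fraction * reference_peak(input_tensor)

  pop_seeds <- derive_seeds(config$seed, config$n_populations)
  dec_seeds <- derive_seeds(config$seed + 1L, 2L)
  acc <- array(NA_real_,
               dim = c(length(sets), 2L, config$n_populations),
               dimnames = list(names(sets), c("surface", "edge"), NULL))
  for (p in seq_len(config$n_populations)) {
    for (s in seq_along(sets)) {
      design <- generate_trial_population(
        sets[[s]], n_sites = config$sites_per_decoder,
        n_trials = config$n_trials, noise_sd = noise_abs,
        seed = pop_seeds[p], noise_scale = "absolute")
      for (loc in c("surface", "edge")) {
        sub <- design_subset(design, location = loc)
        dec <- fit_luminance_decoder(sub, config$lambda, seed = dec_seeds[1])
        acc[s, loc, p] <- rank_accuracy(dec$test_predictions,
                                        dec$test_luminance,
                                        config$n_boot, seed = dec_seeds[2])
      }
    }
  }
  summary <- do.call(rbind, lapply(names(sets), function(cs) {
    do.call(rbind, lapply(c("surface", "edge"), function(loc) {
      a <- acc[cs, loc, ]
      data.frame(condition_set = cs, location = loc,
                 mean_accuracy = mean(a),
                 sem = stats::sd(a) / sqrt(length(a)))
    }))
  }))
  tests <- list(
    edge_input_vs_model_a = paired_compare(acc["input", "edge", ],
                                           acc["model_a", "edge", ]),
    surface_model_a_vs_b = paired_compare(acc["model_a", "surface", ],
                                          acc["model_b", "surface", ]),
    edge_model_a_vs_b = paired_compare(acc["model_a", "edge", ],
                                       acc["model_b", "edge", ])
  )
  structure(list(accuracy = acc, summary = summary, tests = tests,
                 noise_sd = noise_abs, config = config),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("<strategy_result> mean rank accuracy (%) by condition set and location:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("surface model A vs B: mean diff %.2f, p = %.3g\n",
              x$tests$surface_model_a_vs_b$mean_diff,
              x$tests$surface_model_a_vs_b$p_value))
  invisible(x)
}

#' Paired comparison of two accuracy samples
#'
#' Two-sided paired t-test. Identical samples return `t = 0, p = 1`; a
#' constant nonzero difference (zero variance) is flagged degenerate.
#'
#' @param a,b equal-length paired samples.
#' @param alternative passed to the t-test.
#' @return list with `statistic`, `p_value`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
paired_compare <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("paired comparison needs n >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, p_value = 1, mean_diff = 0,
                  n = length(d), degenerate = FALSE))
    warning("zero-variance nonzero difference: p-value degenerate")
    return(list(statistic = Inf * sign(mean(d)), p_value = flagged_na("zero-variance difference"),
                mean_diff = mean(d), n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), n = length(d), degenerate = FALSE)
}

#' Pearson correlation helper
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
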