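#' Write a synthetic dataset to a plain-text dataset directory
#'
#' Canonical on-disk layout: a directory holding `manifest.json` (axes,
#' units, seed, file list), one long-format CSV per tensor
#' (`tensor_<name>.csv` with columns `x, y, l, t, value`; positions in
#' degrees, times in ms), optionally `trials.csv` (columns `trial_id`,
#' `luminance`, `location`, then one `site_*` column per site) and
#' `ground_truth.json`. Numeric values are written with 17 significant
#' digits so a read round trip reproduces the doubles exactly.
#'
#' @param path dataset directory (created).
#' @param tensors named list of [response_tensor()]s.
#' @param design optional `population_design`.
#' @param ground_truth_rec optional [ground_truth()] record.
#' @param seed seed recorded in the manifest.
#' @param overwrite overwrite an existing dataset directory (default
#'   FALSE; rerunning into an existing directory without it is an error).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, tensors, design = NULL, ground_truth_rec = NULL,
                          seed = NA_integer_, overwrite = FALSE) {
  stopifnot(is.list(tensors), length(tensors) > 0, !is.null(names(tensors)))
  if (dir.exists(path)) {
    if (!overwrite) stop("dataset directory exists; pass overwrite = TRUE to replace it")
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  num <- function(x) formatC(x, digits = 17, format = "g")
  for (nm in names(tensors)) {
    tn <- tensors[[nm]]
    stopifnot(inherits(tn, "response_tensor"))
    g <- expand.grid(x = tn$grid$x_centers, y = tn$grid$y_centers,
                     l = tn$luminance, t = tn$time, KEEP.OUT.ATTRS = FALSE)
    dt <- data.table::data.table(x = num(g$x), y = num(g$y), l = g$l,
                                 t = g$t, value = num(as.vector(tn$values)))
    data.table::fwrite(dt, file.path(path, paste0("tensor_", nm, ".csv")))
  }
  if (!is.null(design)) {
    dt <- data.table::data.table(trial_id = seq_len(nrow(design$x)),
                                 luminance = design$luminance,
                                 location = design$location)
    xs <- as.data.frame(apply(design$x, 2, num))
    names(xs) <- sprintf("site_%03d", seq_len(ncol(design$x)))
    data.table::fwrite(cbind(dt, xs), file.path(path, "trials.csv"))
  }
  if (!is.null(ground_truth_rec)) {
    strip_classes <- function(x) if (is.list(x)) lapply(unclass(x), strip_classes) else x
    jsonlite::write_json(strip_classes(ground_truth_rec),
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- list(
    format = "lumicode-dataset", format_version = 1L,
    units = list(space = "deg", time = "ms"),
    seed = seed,
    tensors = lapply(tensors, function(tn) list(
      layer = tn$layer, site_id = tn$site_id,
      bin_width = tn$grid$bin_width,
      n_x = length(tn$grid$x_centers), n_y = length(tn$grid$y_centers),
      luminance = tn$luminance,
      t_min = min(tn$time), t_max = max(tn$time))),
    has_trials = !is.null(design),
    trials = if (!is.null(design)) list(n_trials = design$n_trials,
                                        noise_sd = design$noise_sd,
                                        window = design$window) else NULL
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset directory
#'
#' Validates the manifest (format tag and axis units must be degrees/ms)
#' and the trials column contract, and reconstructs the tensors and the
#' trial design.
#'
#' @param path dataset directory written by [write_dataset()].
#' @return list with `tensors`, `design` (or NULL), `ground_truth` (plain
#'   list or NULL) and `manifest`.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) schema_error("manifest.json missing from dataset directory")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "lumicode-dataset"))
    schema_error("not a lumicode dataset (manifest 'format' field)")
  if (is.null(manifest$units$space) || is.null(manifest$units$time))
    schema_error("manifest missing axis units (units.space / units.time)")
  if (!identical(manifest$units$space, "deg") || !identical(manifest$units$time, "ms"))
    schema_error(sprintf("unexpected axis units: space '%s', time '%s' (need deg/ms)",
                         manifest$units$space, manifest$units$time))
  tensors <- list()
  for (nm in names(manifest$tensors)) {
    f <- file.path(path, paste0("tensor_", nm, ".csv"))
    if (!file.exists(f)) schema_error(sprintf("tensor file missing: %s", basename(f)))
    dt <- data.table::fread(f)
    need <- c("x", "y", "l", "t", "value")
    if (!all(need %in% names(dt)))
      schema_error(sprintf("tensor CSV missing column(s): %s",
                           paste(setdiff(need, names(dt)), collapse = ", ")))
    info <- manifest$tensors[[nm]]
    xs <- sort(unique(dt$x)); ys <- sort(unique(dt$y))
    ls <- sort(unique(dt$l)); ts <- sort(unique(dt$t))
    grid <- spatial_grid(bin_width = info$bin_width, extent = max(xs))
    vals <- array(0, dim = c(length(xs), length(ys), length(ls), length(ts)))
    vals[cbind(match(dt$x, xs), match(dt$y, ys), match(dt$l, ls), match(dt$t, ts))] <- dt$value
    tensors[[nm]] <- response_tensor(vals, grid, luminance = ls, time = ts,
                                     layer = info$layer, site_id = info$site_id)
  }
  design <- NULL
  tf <- file.path(path, "trials.csv")
  if (file.exists(tf)) {
    dt <- data.table::fread(tf)
    need <- c("trial_id", "luminance", "location")
    if (!all(need %in% names(dt)))
      schema_error(sprintf("trials.csv missing column(s): %s",
                           paste(setdiff(need, names(dt)), collapse = ", ")))
    site_cols <- grep("^site_", names(dt), value = TRUE)
    if (length(site_cols) == 0L) schema_error("trials.csv has no site_* response columns")
    design <- structure(
      list(x = as.matrix(dt[, site_cols, with = FALSE]),
           luminance = as.numeric(dt$luminance), location = dt$location,
           n_trials = manifest$trials$n_trials,
           noise_sd = manifest$trials$noise_sd,
           window = unlist(manifest$trials$window)),
      class = "population_design")
  }
  gt <- NULL
  gf <- file.path(path, "ground_truth.json")
  if (file.exists(gf)) gt <- jsonlite::read_json(gf, simplifyVector = TRUE)
  list(tensors = tensors, design = design, ground_truth = gt, manifest = manifest)
}

## ---- run configuration ------------------------------------------------------

config_schema <- list(
  input_params = c("surface_amplitude", "edge_amplitude", "onset_latency",
                   "rise_time", "adaptation_fraction", "adaptation_tau",
                   "black_dominance", "trial_noise_sd"),
  grid = c("bin_width", "extent"),
  model = c("type", "sigma_e", "sigma_i", "w_e_surface", "w_e_edge", "w_i",
            "delay_e", "tsig_e", "delay_i", "tsig_i", "calibrate_ie"),
  population = c("n_sites", "n_trials", "noise_sd", "site_gain_sd",
                 "polarity_sd"),
  decoding = c("lambda", "n_boot"),
  experiment = c("n_populations", "sites_per_decoder", "n_trials",
                 "noise_fraction", "lambda", "n_boot"),
  seed = NULL
)

#' Validate a run configuration
#'
#' Checks a configuration list (typically from a YAML file) against the
#' accepted blocks and keys; unknown blocks or keys are rejected with a
#' schema error naming the offender.
#'
#' @param cfg configuration list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) schema_error("config must be a mapping")
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad))
    schema_error(sprintf("unknown config block(s): %s", paste(bad, collapse = ", ")))
  for (blk in intersect(names(cfg), names(config_schema))) {
    allowed <- config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad))
      schema_error(sprintf("unknown key(s) in config block '%s': %s",
                           blk, paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}
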