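#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic operations in the package draw their seed from a single
#' master seed through this helper, so a pipeline run is reproducible end to
#' end and independent stages do not share RNG streams.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Stop with a classed configuration error (grid/axis problems etc.).
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("lumicode_config_error", "error")))
}

## Stop with a classed schema error for readers/config validation.
schema_error <- function(msg) {
  stop(errorCondition(msg, class = c("lumicode_schema_error", "error")))
}

## Flagged missing value: NA with a reason attribute, used where an index is
## undefined (zero denominators, all-zero responses).
flagged_na <- function(reason) {
  structure(NA_real_, reason = reason)
}

is_flagged_na <- function(x) is.na(x) && !is.null(attr(x, "reason"))
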