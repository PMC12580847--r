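#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif median dist setNames rlnorm optim quantile
#' @importFrom utils read.csv write.csv head tail modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib tsflow, .registration = TRUE
NULL

# Signal a classed error so callers can condition on failure modes
# (mapping_error, parse_error, format_error, dataset_error, feature_error,
#  input_error, config_error, training_error, sampling_error, split_error,
#  fixture_error, empty_core_error).
stop_tsflow <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tsflow_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_tsflow <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "tsflow_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

# Derive a reproducible child seed (kept below 2^31) from a parent seed.
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647
}

centroid <- function(x) colMeans(x)

center_coords <- function(x) {
  sweep(x, 2, colMeans(x))
}

frobenius <- function(x) sqrt(sum(x * x))

`%||%` <- function(a, b) if (is.null(a)) b else a
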