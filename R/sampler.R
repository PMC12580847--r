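# Inference: Euler integration of the probability-flow ODE and median-based
# sample aggregation.

#' Integrate the probability-flow ODE
#'
#' Explicit Euler on a left-endpoint time grid: `x <- x + (1/n_steps) *
#' u(x, k/n_steps)` for `k = 0 .. n_steps-1`, re-centering the centroid after
#' every step so float drift cannot leave the zero-CoM subspace.
#'
#' @param net a `field_net`, or a plain function `f(x, t)` (stub fields in
#'   tests).
#' @param x0 `N x 3` initial coordinates.
#' @param cgr the reaction's `cgr_graph` (ignored for function stubs).
#' @param n_steps number of Euler steps (>= 1).
#' @return `N x 3` coordinates at `t = 1`.
#' @export
integrate_flow <- function(net, x0, cgr = NULL, n_steps = 25) {
  if (n_steps < 1) stop_tsflow("input_error", "n_steps must be >= 1")
  x <- center_coords(as.matrix(x0))
  dt <- 1 / n_steps
  for (k in seq_len(n_steps) - 1L) {
    t_k <- k * dt
    v <- if (is.function(net)) net(x, t_k) else predict_velocity(net, x, t_k, cgr)
    if (any(!is.finite(v))) {
      stop_tsflow("sampling_error", "non-finite field output at step %d", k + 1L)
    }
    x <- center_coords(x + dt * v)
  }
  x
}

#' Aggregate a sample ensemble by median selection
#'
#' Computes the coordinate-wise median geometry over the samples (atoms
#' identified by atom-map number), the Frobenius distance `d_s` of every
#' sample to that median, and returns the sample closest to it. Never touches
#' the ground truth. Ties in the argmin go to the lowest sample index; for an
#' even number of samples the median is the midpoint of the two central
#' values.
#'
#' @param samples list of `N x 3` matrices (same `N`).
#' @return a `sample_ensemble`: `samples`, `median_geometry`, `distances`,
#'   `selected_index`, `final`.
#' @export
aggregate_samples <- function(samples) {
  if (length(samples) < 1) stop_tsflow("input_error", "need at least one sample")
  samples <- lapply(samples, as.matrix)
  dims <- vapply(samples, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3)) {
    stop_tsflow("input_error", "ragged sample shapes")
  }
  arr <- simplify2array(samples)                      # N x 3 x S
  med <- apply(arr, c(1, 2), median)
  d <- vapply(samples, function(s) frobenius(s - med), 0)
  s_star <- which.min(d)                              # ties -> lowest index
  structure(list(
    samples = samples, median_geometry = med, distances = d,
    selected_index = s_star, final = samples[[s_star]]
  ), class = "sample_ensemble")
}

#' @export
print.sample_ensemble <- function(x, ...) {
  cat(sprintf("<sample_ensemble: %d samples, selected #%d (d = %.4f)>\n",
              length(x$samples), x$selected_index, x$distances[x$selected_index]))
  invisible(x)
}

#' Generate TS geometry samples for a reaction
#'
#' Draws `n_samples` base samples, integrates each through the learned flow
#' with `n_samples`-independent noise, and aggregates by median selection.
#' The defaults (`n_samples = 25`, `n_steps = 25`) are the GoFlow-25
#' configuration; `init_mode = "reactant_noise"` gives GoFlow-25-R.
#'
#' @param net a trained `field_net`.
#' @param reaction a `ts_reaction`.
#' @param n_samples ensemble size S.
#' @param n_steps Euler steps per sample.
#' @param init_mode base distribution (see [sample_base()]).
#' @param seed RNG seed; the whole call is deterministic given it.
#' @param cgr optional precomputed `cgr_graph`.
#' @param mutual_align if `TRUE`, Kabsch-align all samples onto the first
#'   before aggregating (off by default: aggregation operates on the raw
#'   sampled frames).
#' @return a `sample_ensemble`.
#' @export
generate <- function(net, reaction, n_samples = 25, n_steps = 25,
                     init_mode = "gaussian", seed = 1, cgr = NULL,
                     mutual_align = FALSE) {
  cgr <- cgr %||% cgr_graph(reaction, elements = net$config$elements)
  samples <- with_seed(seed, {
    xs <- lapply(seq_len(n_samples), function(s)
      center_coords(sample_base(reaction, init_mode)))
    # all samples advance together: one batched field call per Euler step
    dt <- 1 / n_steps
    cgrs <- rep(list(cgr), n_samples)
    for (k in seq_len(n_steps) - 1L) {
      t_k <- k * dt
      vs <- predict_velocity_batch(net, xs, rep(t_k, n_samples), cgrs)
      if (any(vapply(vs, function(v) any(!is.finite(v)), TRUE))) {
        stop_tsflow("sampling_error", "non-finite field output at step %d", k + 1L)
      }
      xs <- Map(function(x, v) center_coords(x + dt * v), xs, vs)
    }
    xs
  })
  if (mutual_align && n_samples > 1) {
    samples <- c(samples[1], lapply(samples[-1], align, x1 = samples[[1]]))
  }
  aggregate_samples(samples)
}
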