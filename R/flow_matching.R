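# Optimal-transport conditional flow matching.
#
# Training pairs couple a base sample x0 with the ground-truth TS geometry x1:
# both are centered at the origin (unweighted centroid) and x0 is rotated onto
# x1 by the Kabsch algorithm (proper rotations only), which straightens the
# linear probability path x_t = (1-t) x0 + t x1. The network regresses the
# constant conditional velocity x1 - x0.

#' Draw a base-distribution sample
#'
#' `gaussian` mode draws i.i.d. standard-normal coordinates; `reactant_noise`
#' mode adds isotropic Gaussian noise with variance `sigma2` per coordinate
#' (default 0.25, i.e. sd 0.5 Angstrom) to the reactant geometry. Either way
#' the result is centroid-centered. Uses the current RNG state; seed at the
#' call site for reproducibility.
#'
#' @param reaction a `ts_reaction`.
#' @param mode `"gaussian"` or `"reactant_noise"`.
#' @param sigma2 per-coordinate noise variance for `reactant_noise` mode.
#' @return `N x 3` CoM-centered coordinate matrix.
#' @export
sample_base <- function(reaction, mode = c("gaussian", "reactant_noise"), sigma2 = 0.25) {
  mode <- match.arg(mode)
  nn <- reaction$n_atoms
  x0 <- if (mode == "gaussian") {
    matrix(rnorm(3 * nn), nn, 3)
  } else {
    if (is.null(reaction$reactant_geometry)) {
      stop_tsflow("config_error", "reactant_noise init requires a reactant geometry (%s)",
                  reaction$rxn_id)
    }
    reaction$reactant_geometry$coords + matrix(rnorm(3 * nn, sd = sqrt(sigma2)), nn, 3)
  }
  center_coords(x0)
}

# Optimal proper rotation (det +1) mapping centered A onto centered B.
kabsch_rotation <- function(A, B) {
  M <- t(A) %*% B
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Kabsch-align one point set onto another
#'
#' Centers `x0`, then rotates it by the proper rotation (determinant +1)
#' minimizing the Frobenius distance to centered `x1`. Reflections are never
#' applied, so a chiral set cannot be aligned onto its mirror image.
#'
#' @param x0 `N x 3` matrix to align.
#' @param x1 `N x 3` reference (centered internally for the fit; the return
#'   value is in the centered frame).
#' @return the aligned, centered `x0`.
#' @export
align <- function(x0, x1) {
  x0 <- as.matrix(x0); x1 <- as.matrix(x1)
  if (!all(dim(x0) == dim(x1)) || ncol(x0) != 3) {
    stop_tsflow("input_error", "align needs two N x 3 matrices of equal shape")
  }
  x0c <- center_coords(x0)
  x1c <- center_coords(x1)
  R <- kabsch_rotation(x0c, x1c)
  x0c %*% R
}

#' Build one conditional flow-matching pair
#'
#' @param reaction a `ts_reaction` with a TS geometry.
#' @param t flow time in `[0, 1]`.
#' @param x0 base sample (will be aligned onto the TS coordinates).
#' @param cgr optional precomputed `cgr_graph`.
#' @return a `flow_pair`: `x0` (aligned), `x1` (centered TS), `t`, the
#'   interpolant `x_t = (1-t) x0 + t x1`, and `v_target = x1 - x0`.
#' @export
flow_pair <- function(reaction, t, x0, cgr = NULL) {
  if (is.null(reaction$ts_geometry)) {
    stop_tsflow("input_error", "reaction %s has no TS geometry", reaction$rxn_id)
  }
  x1 <- center_coords(reaction$ts_geometry$coords)
  x0a <- align(x0, x1)
  structure(list(
    x0 = x0a, x1 = x1, t = t,
    x_t = (1 - t) * x0a + t * x1,
    v_target = x1 - x0a,
    cgr = cgr %||% cgr_graph(reaction)
  ), class = "flow_pair")
}

#' Conditional flow-matching loss
#'
#' Mean over pairs and atoms of the squared residual
#' `|u_theta(x_t, t) - (x1 - x0)|^2`.
#'
#' @param net a `field_net`, or a plain function `f(x, t)` used as a stub
#'   field in tests.
#' @param pairs list of `flow_pair`.
#' @return non-negative scalar.
#' @export
cfm_loss <- function(net, pairs) {
  if (is.function(net)) {
    total <- vapply(pairs, function(p) {
      sum((net(p$x_t, p$t) - p$v_target)^2) / nrow(p$x_t)
    }, 0)
    return(mean(total))
  }
  cfm_loss_grad(net, pairs, want_grads = FALSE)$loss
}

# Loss (+ parameter gradients) over a batch of pairs, in one kernel call.
# space = "velocity" is the conditional flow-matching loss itself;
# "displacement" regresses the raw network output against the remaining
# displacement (1-t)(x1-x0) with uniform weight across flow times. Both
# objectives share the same pointwise minimizer; the displacement form avoids
# the 1/(1-t)^2 weighting that otherwise concentrates the stochastic gradient
# on late flow times, and is what the optimizer sees during training.
cfm_loss_grad <- function(net, pairs, want_grads = TRUE,
                          space = c("velocity", "displacement")) {
  space <- match.arg(space)
  batch <- batch_graph(net, lapply(pairs, `[[`, "x_t"), lapply(pairs, `[[`, "t"),
                       lapply(pairs, `[[`, "cgr"))
  target <- do.call(rbind, lapply(pairs, `[[`, "v_target"))
  if (space == "displacement") {
    fac <- rep(1 - vapply(pairs, `[[`, 0, "t"), batch$sizes)
    target <- target * fac
    batch$tscale <- rep(1, length(batch$tscale))
  }
  # per-atom weights: mean over atoms within a reaction, mean over reactions
  w <- rep(1 / (batch$sizes * length(pairs)), batch$sizes)
  fieldnet_loss_grad(net, batch, target, w, want_grads)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       step = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$step)
    vhat <- state$v[[nm]] / (1 - beta2^state$step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param epochs passes over the dataset.
#' @param batch_size reactions per gradient step.
#' @param lr Adam learning rate.
#' @param seed RNG seed fixing all sampling in the run.
#' @param init_mode base distribution: `"gaussian"` or `"reactant_noise"`.
#' @param sigma2 reactant-noise variance (0.25 by default).
#' @param n_draws independent `(t, x0)` draws per reaction per epoch
#'   (variance reduction; 1 by default).
#' @param lr_schedule `"cosine"` (linear warmup over the first 5% of steps,
#'   then cosine decay to near zero — the default) or `"constant"`.
#' @param clip_norm global gradient-norm clip (`Inf` to disable).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 128, lr = 2e-3, seed = 1,
                         init_mode = "gaussian", sigma2 = 0.25, n_draws = 1,
                         lr_schedule = c("cosine", "constant"), clip_norm = 10) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed), init_mode = init_mode,
                 sigma2 = sigma2, n_draws = as.integer(n_draws),
                 lr_schedule = match.arg(lr_schedule), clip_norm = clip_norm),
            class = "train_config")
}

clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (total > clip_norm) grads <- lapply(grads, function(g) g * clip_norm / total)
  grads
}

schedule_lr <- function(base_lr, step, total_steps, schedule) {
  if (schedule == "constant") return(base_lr)
  warmup <- max(1, ceiling(0.05 * total_steps))
  if (step <= warmup) return(base_lr * step / warmup)
  prog <- (step - warmup) / max(1, total_steps - warmup)
  base_lr * 0.5 * (1 + cos(pi * prog)) + 1e-6
}

#' Train the field network by conditional flow matching
#'
#' Per epoch and batch: draw `t ~ U(0,1)` (one per reaction draw), draw a base
#' sample, Kabsch-align it onto the centered TS coordinates, form the linear
#' interpolant and the constant target velocity `x1 - x0`, and take one Adam
#' step on the CFM loss. Deterministic given `config$seed`.
#'
#' @param dataset list of `ts_reaction`, all with TS geometries.
#' @param net a `field_net`.
#' @param config a [train_config()].
#' @param log_path optional path for a JSON-lines loss log.
#' @param verbose print per-epoch loss.
#' @return list with the trained `net` and the per-epoch `loss_curve`.
#' @export
train <- function(dataset, net, config = train_config(), log_path = NULL,
                  verbose = FALSE) {
  if (length(dataset) == 0) stop_tsflow("config_error", "empty training dataset")
  for (r in dataset) {
    if (is.null(r$ts_geometry)) {
      stop_tsflow("config_error", "reaction %s lacks a TS geometry", r$rxn_id)
    }
    if (config$init_mode == "reactant_noise" && is.null(r$reactant_geometry)) {
      stop_tsflow("config_error", "reaction %s lacks a reactant geometry", r$rxn_id)
    }
  }
  cgrs <- lapply(dataset, cgr_graph, elements = net$config$elements)
  params <- net$params
  state <- adam_state(params)
  loss_curve <- numeric(config$epochs)
  con <- if (!is.null(log_path)) file(log_path, "w") else NULL
  on.exit(if (!is.null(con)) close(con), add = TRUE)

  steps_per_epoch <- ceiling(length(dataset) * config$n_draws / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  global_step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- rep(sample(length(dataset)), each = config$n_draws)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      epoch_loss <- 0
      t0 <- proc.time()[[3]]
      for (batch in batches) {
        net$params <- params
        pairs <- lapply(batch, function(k) {
          x0 <- sample_base(dataset[[k]], config$init_mode, config$sigma2)
          flow_pair(dataset[[k]], runif(1), x0, cgr = cgrs[[k]])
        })
        lg <- cfm_loss_grad(net, pairs, space = "displacement")
        if (!is.finite(lg$loss)) {
          stop_tsflow("training_error", "divergent (non-finite) loss at epoch %d", epoch)
        }
        global_step <- global_step + 1L
        lr_now <- schedule_lr(config$lr, global_step, total_steps, config$lr_schedule)
        upd <- adam_step(params, clip_gradients(lg$grads, config$clip_norm), state, lr_now)
        params <- upd$params; state <- upd$state
        epoch_loss <- epoch_loss + lg$loss * length(batch)
      }
      loss_curve[epoch] <- epoch_loss / length(idx)
      if (!is.null(con)) {
        writeLines(jsonlite::toJSON(list(
          epoch = epoch, loss = loss_curve[epoch], lr = config$lr,
          wall_s = proc.time()[[3]] - t0
        ), auto_unbox = TRUE, digits = NA), con)
      }
      if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch, loss_curve[epoch]))
    }
  })
  net$params <- params
  list(net = net, loss_curve = loss_curve)
}

#' Save a field-network checkpoint
#'
#' Plain-text archive: a JSON header with the architecture config followed by
#' the flattened parameters (full double precision).
#'
#' @param net a `field_net`.
#' @param path output path.
#' @export
save_checkpoint <- function(net, path) {
  jsonlite::write_json(list(
    format = "tsflow-checkpoint-v1",
    config = net$config,
    params = net$params
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Load a field-network checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return a `field_net`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tsflow-checkpoint-v1")) {
    stop_tsflow("format_error", "not a tsflow checkpoint: %s", path)
  }
  cfg <- obj$config
  cfg$elements <- as.character(cfg$elements)
  net <- field_net(width = cfg$width, n_layers = cfg$n_layers, l_max = cfg$l_max,
                   n_channels = cfg$n_channels, n_rbf = cfg$n_rbf,
                   cutoff = cfg$cutoff, max_hops = cfg$max_hops,
                   elements = cfg$elements, hidden_mult = cfg$hidden_mult)
  params <- obj$params
  for (nm in names(net$params)) {
    p <- params[[nm]]
    if (is.null(p)) stop_tsflow("format_error", "checkpoint missing parameter %s", nm)
    if (is.matrix(net$params[[nm]])) {
      p <- matrix(as.numeric(t(p)), nrow(net$params[[nm]]), ncol(net$params[[nm]]),
                  byrow = TRUE)
    } else {
      p <- as.numeric(p)
    }
    net$params[[nm]] <- p
  }
  net
}
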