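# Time-conditioned E(3)-equivariant vector-field network u_theta(x, t | CGR).
#
# Message-passing network with invariant scalar features on nodes and edges
# plus steerable features up to degree L_max, built from spherical harmonics
# of the edge directions — no Clebsch-Gordan tensor products. Every geometric
# quantity enters through relative vectors r_ij, so the predicted per-atom
# velocities are translation-invariant and rotation/reflection-equivariant by
# construction: degree-1 channels and the direct edge term transform as
# vectors, degree-2 channels feed back only through O(3)-invariant channel
# norms.

#' Construct an equivariant field network
#'
#' @param width scalar feature width (atom basis). Default 256, the best
#'   configuration of the parameter ablation; tests and desk-scale runs use
#'   smaller widths.
#' @param n_layers number of message-passing layers.
#' @param l_max maximum spherical-harmonic degree of the steerable features
#'   (1 or 2).
#' @param n_channels number of steerable channels per degree (default
#'   `width / 4`).
#' @param n_rbf number of Gaussian radial basis functions on `[0, cutoff]`.
#' @param cutoff radius cutoff in Angstrom for geometry edges.
#' @param max_hops hop cutoff for graph edges.
#' @param elements element palette (must match the CGR featurization).
#' @param hidden_mult hidden-layer width multiplier in the MLPs.
#' @param t_floor floor on `1 - t` in the displacement-to-velocity rescaling
#'   (bounds both the inference-time contraction strength and the implicit
#'   loss weighting across flow times).
#' @param seed RNG seed for parameter initialization.
#' @return an object of class `field_net` holding `config` and `params`.
#' @export
field_net <- function(width = 256, n_layers = 4, l_max = 2,
                      n_channels = NULL, n_rbf = 16, cutoff = 10,
                      max_hops = 3, elements = DEFAULT_ELEMENTS,
                      hidden_mult = 2, t_floor = 0.04, seed = 1) {
  if (!l_max %in% c(1, 2)) stop_tsflow("config_error", "l_max must be 1 or 2")
  n_channels <- n_channels %||% max(4L, as.integer(width / 4))
  cfg <- list(width = as.integer(width), n_layers = as.integer(n_layers),
              l_max = as.integer(l_max), n_channels = as.integer(n_channels),
              n_rbf = as.integer(n_rbf), cutoff = cutoff, max_hops = max_hops,
              elements = elements, hidden_mult = hidden_mult, t_floor = t_floor,
              n_atom_feat = length(elements) + 18L + 3L, n_bond_feat = 10L)
  params <- with_seed(seed, init_params(cfg))
  structure(list(config = cfg, params = params), class = "field_net")
}

init_params <- function(cfg) {
  w <- cfg$width; hw <- as.integer(cfg$hidden_mult * w); c <- cfg$n_channels
  p <- list()
  lin <- function(nin, nout, scale = 1) {
    matrix(rnorm(nin * nout) * scale * sqrt(1 / nin), nin, nout)
  }
  p$W_node <- lin(cfg$n_atom_feat, w); p$b_node <- numeric(w)
  p$W_edge <- lin(cfg$n_bond_feat, w); p$b_edge <- numeric(w)
  p$W_rbf <- lin(cfg$n_rbf, w)
  # learned injection of CoM-frame positions into the degree-1 channels
  p$pos_W <- matrix(0.5, 1, cfg$n_channels)
  # canonical-frame output head (invariant coefficients on the frame vectors)
  p$frame_W <- lin(w, 3L, 0.1); p$frame_b <- numeric(3L)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d_", l)
    p[[paste0(pre, "ln_h_g")]] <- rep(1, w); p[[paste0(pre, "ln_h_b")]] <- numeric(w)
    p[[paste0(pre, "ln_e_g")]] <- rep(1, w); p[[paste0(pre, "ln_e_b")]] <- numeric(w)
    p[[paste0(pre, "msg_W1")]] <- lin(3L * w + 2L, hw); p[[paste0(pre, "msg_b1")]] <- numeric(hw)
    p[[paste0(pre, "msg_W2")]] <- lin(hw, w); p[[paste0(pre, "msg_b2")]] <- numeric(w)
    p[[paste0(pre, "edge_W")]] <- lin(w, w, 0.5); p[[paste0(pre, "edge_b")]] <- numeric(w)
    p[[paste0(pre, "upd_W1")]] <- lin(2L * w + cfg$l_max * c + 2L, hw)
    p[[paste0(pre, "upd_b1")]] <- numeric(hw)
    p[[paste0(pre, "upd_W2")]] <- lin(hw, w, 0.5); p[[paste0(pre, "upd_b2")]] <- numeric(w)
    for (l2 in seq_len(cfg$l_max)) {
      p[[sprintf("%ssca%d_W", pre, l2)]] <- lin(w, c)
      p[[sprintf("%ssca%d_b", pre, l2)]] <- numeric(c)
      p[[sprintf("%sgate%d_W", pre, l2)]] <- lin(w, c)
      p[[sprintf("%sgate%d_b", pre, l2)]] <- numeric(c)
    }
    # per-layer output head: coefficients for the unit and the distance-scaled
    # relative edge vector
    p[[paste0(pre, "out_W")]] <- lin(w, 2L, 0.1)
    p[[paste0(pre, "out_b")]] <- numeric(2L)
  }
  p$out_v_W <- lin(c, 1L, 0.1)
  p
}

#' Count trainable parameters
#'
#' @param net a `field_net`.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, 1L))
}

#' @export
print.field_net <- function(x, ...) {
  cat(sprintf("<field_net: width %d, %d layers, L_max %d, %s parameters>\n",
              x$config$width, x$config$n_layers, x$config$l_max,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Gaussian radial basis of distances on [0, cutoff].
radial_basis <- function(d, n_rbf, cutoff) {
  centers <- seq(0, cutoff, length.out = n_rbf)
  delta <- centers[2] - centers[1]
  exp(-((outer(d, centers, "-")) / delta)^2)
}

# Real orthonormal degree-2 spherical-harmonic components of unit vectors
# (coefficients of the traceless symmetric tensor u u^T in an orthonormal
# basis, so rotations and reflections act orthogonally on them).
sh_degree2 <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(sqrt(2) * x * y,
        sqrt(2) * y * z,
        sqrt(2) * x * z,
        (x^2 - y^2) / sqrt(2),
        sqrt(1.5) * (z^2 - 1 / 3))
}

# Geometry-derived constants for one network call.
edge_geometry <- function(coords, edge_index, cfg) {
  a <- edge_index[, 1]; b <- edge_index[, 2]
  rel <- coords[b, , drop = FALSE] - coords[a, , drop = FALSE]
  d <- sqrt(rowSums(rel^2))
  d <- pmax(d, 1e-10)
  u <- rel / d
  list(recv = a, send = b, d = d, u = u,
       rbf = radial_basis(d, cfg$n_rbf, cfg$cutoff),
       y2 = if (cfg$l_max >= 2) sh_degree2(u) else NULL)
}

# Assemble the disjoint union of several (coords, t, cgr) instances into one
# batch graph: node rows are concatenated, edge indices offset, and per-graph
# quantities (time embedding, velocity rescaling) expanded to node/edge rows.
batch_graph <- function(net, coords_list, t_list, cgr_list, edge_list = NULL) {
  cfg <- net$config
  n_g <- length(coords_list)
  sizes <- as.integer(vapply(cgr_list, function(g) as.numeric(g$n_atoms), 0))
  offsets <- c(0L, cumsum(sizes))
  af <- list(); ef <- list(); ei <- list(); tn <- list(); te <- list()
  tcn <- list(); tce <- list(); fn <- list()
  tscale <- numeric(0)
  for (g in seq_len(n_g)) {
    x <- coords_list[[g]]
    if (any(!is.finite(x))) stop_tsflow("input_error", "non-finite coordinates in field input")
    t <- t_list[[g]]
    if (t < 0 || t > 1) stop_tsflow("input_error", "t must lie in [0,1]")
    e <- if (is.null(edge_list)) {
      build_edge_set(cgr_list[[g]], x, cfg$cutoff, cfg$max_hops)
    } else edge_list[[g]]
    temb <- time_embedding(t, cfg$width)
    af[[g]] <- cgr_list[[g]]$node_features
    ef[[g]] <- edge_feature_matrix(cgr_list[[g]], e)
    ei[[g]] <- e + offsets[g]
    tn[[g]] <- matrix(temb, sizes[g], cfg$width, byrow = TRUE)
    te[[g]] <- matrix(temb, nrow(e), cfg$width, byrow = TRUE)
    tcn[[g]] <- matrix(c(t, 1 - t), sizes[g], 2, byrow = TRUE)
    tce[[g]] <- matrix(c(t, 1 - t), nrow(e), 2, byrow = TRUE)
    tscale <- c(tscale, rep(1 / max(1 - t, cfg$t_floor), sizes[g]))
    fr <- canonical_frame(x)
    af[[g]] <- cbind(af[[g]], fr$proj)
    fn[[g]] <- matrix(as.numeric(fr$frame), sizes[g], 9, byrow = TRUE)
  }
  list(coords = do.call(rbind, coords_list),
       edge_index = do.call(rbind, ei),
       node_features = do.call(rbind, af),
       edge_features = do.call(rbind, ef),
       temb_node = do.call(rbind, tn),
       temb_edge = do.call(rbind, te),
       tc_node = do.call(rbind, tcn),
       tc_edge = do.call(rbind, tce),
       frame_rows = do.call(rbind, fn),
       t_list = unlist(t_list),
       tscale = tscale, sizes = sizes, offsets = offsets, n_graphs = n_g)
}

# Per-graph CoM-centered coordinates (degree-1 channel initialization).
batch_center <- function(batch) {
  ctr <- batch$coords
  for (g in seq_len(batch$n_graphs)) {
    rows <- (batch$offsets[g] + 1):batch$offsets[g + 1]
    ctr[rows, ] <- sweep(batch$coords[rows, , drop = FALSE], 2,
                         colMeans(batch$coords[rows, , drop = FALSE]))
  }
  ctr
}

# Canonical global frame of a point cloud: eigenvectors of the position
# covariance, ordered by descending eigenvalue, signs fixed by the third
# moment of the projections. The frame transforms covariantly under any
# orthogonal transform of the coordinates (proper or improper), so invariant
# projections plus frame-vector outputs preserve exact E(3)-equivariance.
# Degenerate spectra (exactly symmetric clouds) make the frame arbitrary
# within the degenerate subspace; generic molecular geometries are safe.
canonical_frame <- function(coords) {
  ctr <- sweep(coords, 2, colMeans(coords))
  C <- crossprod(ctr) / nrow(ctr)
  eg <- eigen(C, symmetric = TRUE)      # eigenvalues descending
  E <- eg$vectors
  proj <- ctr %*% E
  for (k in 1:3) {
    s3 <- sum(proj[, k]^3)
    if (s3 < 0) { E[, k] <- -E[, k]; proj[, k] <- -proj[, k] }
  }
  list(frame = E, proj = proj)          # frame columns are e_1..e_3
}

cpp_config <- function(cfg) {
  list(width = cfg$width, n_layers = cfg$n_layers, l_max = cfg$l_max,
       n_channels = cfg$n_channels, n_rbf = cfg$n_rbf, cutoff = cfg$cutoff,
       hidden_mult = cfg$hidden_mult)
}

# Batched forward through the compiled kernel; returns the stacked N x 3
# velocity matrix for the whole batch graph.
fieldnet_forward <- function(net, batch) {
  .fn_forward(net$params, cpp_config(net$config), batch$coords,
              batch$edge_index - 1L, batch$node_features, batch$edge_features,
              batch$temb_node, batch$temb_edge, batch$tc_node, batch$tc_edge,
              batch$frame_rows, batch$tscale, batch_center(batch))
}

# CFM loss (and parameter gradients) for a prepared batch + stacked targets.
fieldnet_loss_grad <- function(net, batch, target, wrow, want_grads = TRUE) {
  out <- .fn_loss_grad(net$params, cpp_config(net$config), batch$coords,
                       batch$edge_index - 1L, batch$node_features,
                       batch$edge_features, batch$temb_node, batch$temb_edge,
                       batch$tc_node, batch$tc_edge, batch$frame_rows,
                       batch$tscale, batch_center(batch), target, wrow,
                       want_grads)
  if (want_grads) {
    # match parameter shapes (vector parameters come back as 1 x k matrices)
    for (nm in names(out$grads)) {
      if (!is.matrix(net$params[[nm]])) out$grads[[nm]] <- as.numeric(out$grads[[nm]])
    }
  }
  out
}

# Batched field evaluation: list of coordinate matrices with per-element
# times and CGRs. Returns a list of N x 3 velocity matrices.
predict_velocity_batch <- function(net, coords_list, t_list, cgr_list) {
  batch <- batch_graph(net, coords_list, t_list, cgr_list)
  v <- fieldnet_forward(net, batch)
  lapply(seq_len(batch$n_graphs), function(g) {
    v[(batch$offsets[g] + 1):batch$offsets[g + 1], , drop = FALSE]
  })
}

#' Evaluate the equivariant vector field
#'
#' Computes the per-atom velocity `u_theta(x, t | CGR)` in Angstrom per unit
#' flow time. The output is translation-invariant, equivariant under rotations
#' and reflections of `coords`, and permutation-covariant.
#'
#' @param net a `field_net`.
#' @param coords `N x 3` coordinate matrix (current flow state, CoM-centered
#'   by the callers in this package).
#' @param t flow time in `[0, 1]`.
#' @param cgr the reaction's `cgr_graph`.
#' @param edge_index optional fixed edge set; by default edges are recomputed
#'   from `coords` at every call.
#' @return `N x 3` velocity matrix.
#' @export
predict_velocity <- function(net, coords, t, cgr, edge_index = NULL) {
  batch <- batch_graph(net, list(coords), list(t), list(cgr),
                       if (is.null(edge_index)) NULL else list(edge_index))
  v <- fieldnet_forward(net, batch)
  if (any(!is.finite(v))) stop_tsflow("sampling_error", "non-finite field output")
  v
}
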