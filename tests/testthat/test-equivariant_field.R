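test_that("field output is exactly E(3)-equivariant and permutation-covariant", {
  set.seed(7)
  net <- tiny_net()
  rxn <- small_dataset()[[1]]
  cgr <- cgr_graph(rxn)
  x <- rxn$ts_geometry$coords
  v <- predict_velocity(net, x, 0.5, cgr)
  expect_equal(dim(v), c(rxn$n_atoms, 3))

  for (k in 1:5) {
    R <- random_rotation()
    expect_lt(max(abs(predict_velocity(net, x %*% R, 0.5, cgr) - v %*% R)), 1e-10)
    S <- random_reflection()
    expect_lt(max(abs(predict_velocity(net, x %*% S, 0.5, cgr) - v %*% S)), 1e-10)
    tr <- rnorm(3, sd = 5)
    expect_lt(max(abs(predict_velocity(net, sweep(x, 2, tr, "+"), 0.5, cgr) - v)), 1e-10)
  }
})

test_that("mirror input gives mirrored output (chirality failure mode)", {
  net <- tiny_net(seed = 8)
  pair <- make_chiral_pair(seed = 2)
  cgr <- cgr_graph(pair$reaction)
  x <- pair$reaction$ts_geometry$coords
  S <- diag(c(-1, 1, 1))
  v <- predict_velocity(net, x, 0.3, cgr)
  vm <- predict_velocity(net, x %*% S, 0.3, cgr)
  expect_lt(max(abs(vm - v %*% S)), 1e-10)
})

test_that("permuting atoms (and the graph) permutes output rows", {
  net <- tiny_net()
  s1 <- "[C:1]([H:3])([H:4])([H:5])[O:2][H:6]>>[C:1]([H:3])([H:4])=[O:2].[H:5].[H:6]"
  s2 <- "[C:2]([H:6])([H:4])([H:5])[O:1][H:3]>>[C:2]([H:6])([H:4])=[O:1].[H:5].[H:3]"
  r1 <- parse_reaction(s1); r2 <- parse_reaction(s2)
  perm <- c(2, 1, 6, 4, 5, 3)    # atom perm[i] of r1 is atom i of r2
  set.seed(9)
  x1 <- matrix(rnorm(18), 6, 3)
  x2 <- x1[perm, ]
  v1 <- predict_velocity(net, x1, 0.4, cgr_graph(r1))
  v2 <- predict_velocity(net, x2, 0.4, cgr_graph(r2))
  expect_lt(max(abs(v2 - v1[perm, ])), 1e-10)
})

test_that("output is independent of edge ordering", {
  net <- tiny_net()
  rxn <- small_dataset()[[2]]
  cgr <- cgr_graph(rxn)
  x <- rxn$ts_geometry$coords
  ei <- build_edge_set(cgr, x, net$config$cutoff, net$config$max_hops)
  set.seed(10)
  shuf <- ei[sample(nrow(ei)), ]
  v1 <- predict_velocity(net, x, 0.6, cgr, edge_index = ei)
  v2 <- predict_velocity(net, x, 0.6, cgr, edge_index = shuf)
  expect_lt(max(abs(v1 - v2)), 1e-12)
})

test_that("parameter counting is monotone and hits the reported magnitude", {
  n64 <- field_net(width = 64, seed = 1)
  n128 <- field_net(width = 128, seed = 1)
  expect_gt(count_parameters(n128), count_parameters(n64))
  # published full-size configuration: ~5e6 parameters at width 256
  n256 <- field_net(width = 256, seed = 1)
  expect_gt(count_parameters(n256), 1e6)
  expect_lt(count_parameters(n256), 2e7)
  # zero layers: embeddings + heads only
  n0 <- field_net(width = 32, n_layers = 0, seed = 1)
  expect_equal(count_parameters(n0),
               sum(lengths(n0$params[c("W_node", "b_node", "W_edge", "b_edge",
                                       "W_rbf", "pos_W", "frame_W", "frame_b",
                                       "out_v_W")])))
})

test_that("analytic parameter gradients match finite differences", {
  net <- tiny_net(width = 12, n_layers = 2)
  rxn <- small_dataset()[[3]]
  cgr <- cgr_graph(rxn)
  set.seed(11)
  pair <- flow_pair(rxn, 0.45, sample_base(rxn, "gaussian"), cgr)
  lg <- tsflow:::cfm_loss_grad(net, list(pair))
  expect_gt(lg$loss, 0)
  eps <- 1e-6
  set.seed(12)
  for (nm in sample(names(lg$grads), 10)) {
    k <- sample(length(net$params[[nm]]), 1)
    n2 <- net
    n2$params[[nm]][k] <- net$params[[nm]][k] + eps
    lp <- cfm_loss(n2, list(pair))
    n2$params[[nm]][k] <- net$params[[nm]][k] - eps
    lm <- cfm_loss(n2, list(pair))
    num <- (lp - lm) / (2 * eps)
    expect_equal(lg$grads[[nm]][k], num, tolerance = 1e-4,
                 label = sprintf("grad of %s[%d]", nm, k))
  }
})

test_that("field input validation rejects non-finite coordinates", {
  net <- tiny_net()
  rxn <- small_dataset()[[1]]
  cgr <- cgr_graph(rxn)
  x <- rxn$ts_geometry$coords
  x[2, 1] <- NaN
  expect_error(predict_velocity(net, x, 0.5, cgr), class = "input_error")
  expect_error(predict_velocity(net, rxn$ts_geometry$coords, 1.5, cgr),
               class = "input_error")
})

test_that("checkpoints round-trip parameters to full working precision", {
  net <- tiny_net(seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(net2$config$width, net$config$width)
  for (nm in names(net$params)) {
    expect_equal(net2$params[[nm]], net$params[[nm]], tolerance = 1e-12,
                 label = nm)
  }
  rxn <- small_dataset()[[1]]
  cgr <- cgr_graph(rxn)
  x <- rxn$ts_geometry$coords
  expect_equal(predict_velocity(net2, x, 0.5, cgr),
               predict_velocity(net, x, 0.5, cgr), tolerance = 1e-10)
})
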