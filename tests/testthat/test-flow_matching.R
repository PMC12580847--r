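test_that("base samples are centered and reproducible", {
  rxn <- small_dataset()[[1]]
  set.seed(5)
  x0a <- sample_base(rxn, "gaussian")
  set.seed(5)
  x0b <- sample_base(rxn, "gaussian")
  expect_identical(x0a, x0b)
  expect_lt(sqrt(sum(colMeans(x0a)^2)), 1e-6)

  rxn_nore <- rxn
  rxn_nore$reactant_geometry <- NULL
  expect_error(sample_base(rxn_nore, "reactant_noise"), class = "config_error")
})

test_that("reactant-noise base has per-coordinate sd 0.5 A (sigma^2 = 0.25)", {
  rxn <- small_dataset()[[1]]
  set.seed(6)
  # deviations from the (centered) reactant geometry; centering removes a
  # 3-dof mean per draw, handled by the dof correction below
  re <- center_coords(rxn$reactant_geometry$coords)
  n_draw <- 10000
  devs <- replicate(n_draw, sample_base(rxn, "reactant_noise", sigma2 = 0.25) - re)
  sd_hat <- sd(as.numeric(devs)) * sqrt(rxn$n_atoms / (rxn$n_atoms - 1))
  expect_equal(sd_hat, 0.5, tolerance = 0.02)
})

test_that("align recovers proper rigid motions exactly", {
  set.seed(13)
  for (k in 1:5) {
    x1 <- matrix(rnorm(21, sd = 2), 7, 3)
    R <- random_rotation()
    x0 <- sweep(x1 %*% R, 2, rnorm(3, sd = 4), "+")
    aligned <- align(x0, x1)
    expect_lt(sqrt(mean(rowSums((aligned - center_coords(x1))^2))), 1e-6)
  }
  expect_error(align(matrix(0, 3, 3), matrix(0, 4, 3)), class = "input_error")
})

test_that("align is optimal against a random-rotation oracle", {
  set.seed(14)
  for (k in 1:10) {
    x0 <- matrix(rnorm(15, sd = 1.5), 5, 3)
    x1 <- matrix(rnorm(15, sd = 1.5), 5, 3)
    x1c <- center_coords(x1)
    res_align <- sum((align(x0, x1) - x1c)^2)
    x0c <- center_coords(x0)
    res_rand <- min(vapply(1:2000, function(i) {
      sum((x0c %*% random_rotation() - x1c)^2)
    }, 0))
    expect_lte(res_align, res_rand + 1e-9)
  }
})

test_that("align never applies reflections (chiral mirror keeps residual)", {
  pair <- make_chiral_pair(seed = 3)
  orig <- pair$reaction$ts_geometry$coords
  mirr <- pair$mirror$coords
  aligned <- align(mirr, orig)
  expect_gt(sqrt(mean(rowSums((aligned - center_coords(orig))^2))), 0.1)
})

test_that("flow pairs sit exactly on the linear interpolant", {
  rxn <- small_dataset()[[2]]
  set.seed(15)
  p <- flow_pair(rxn, 0.3, sample_base(rxn, "gaussian"))
  expect_equal(p$x_t, 0.7 * p$x0 + 0.3 * p$x1)
  expect_equal(p$v_target, p$x1 - p$x0)
  expect_lt(sqrt(sum(colMeans(p$x0)^2)), 1e-6)
  expect_lt(sqrt(sum(colMeans(p$x1)^2)), 1e-6)
})

test_that("alignment reduces expected transport cost", {
  rxn <- small_dataset()[[3]]
  x1c <- center_coords(rxn$ts_geometry$coords)
  set.seed(16)
  costs <- replicate(40, {
    x0 <- sample_base(rxn, "gaussian")
    c(aligned = sum((align(x0, x1c) - x1c)^2),
      raw = sum((center_coords(x0) - x1c)^2))
  })
  expect_lt(mean(costs["aligned", ]), mean(costs["raw", ]))
  # alignment never hurts on any single pair
  expect_true(all(costs["aligned", ] <= costs["raw", ] + 1e-9))
})

test_that("cfm loss matches closed forms for stub fields", {
  rxn <- small_dataset()[[1]]
  set.seed(17)
  pairs <- lapply(1:3, function(k) flow_pair(rxn, runif(1), sample_base(rxn, "gaussian")))
  oracle <- function(p) {
    force(p)
    function(x, t) p$v_target
  }
  # stub returning the exact target: zero loss (evaluated pair by pair)
  for (p in pairs) expect_equal(cfm_loss(oracle(p), list(p)), 0)
  # zero field: loss is the mean squared target norm
  zero_field <- function(x, t) x * 0
  expected <- mean(vapply(pairs, function(p) sum(p$v_target^2) / nrow(p$x_t), 0))
  expect_equal(cfm_loss(zero_field, pairs), expected)
  # hand-computed 2-atom case with a constant stub
  p2 <- list(x_t = matrix(0, 2, 3), t = 0.5,
             v_target = rbind(c(1, 0, 0), c(0, 2, 0)))
  const_field <- function(x, t) rbind(c(0.5, 0, 0), c(0, 0, 0))
  # residuals: (0.5,0,0)-(1,0,0) -> 0.25 ; (0,0,0)-(0,2,0) -> 4 ; mean/atom = 2.125
  expect_equal(cfm_loss(const_field, list(p2)), (0.25 + 4) / 2)
})

test_that("training is deterministic, loggable, and rejects bad input", {
  ds <- small_dataset()[1:2]
  net <- tiny_net(width = 12, n_layers = 1, seed = 31)
  cfg <- train_config(epochs = 3, batch_size = 2, lr = 1e-3, seed = 42)
  log_path <- withr::local_tempfile(fileext = ".jsonl")
  r1 <- train(ds, net, cfg, log_path = log_path)
  r2 <- train(ds, net, cfg)
  expect_equal(r1$loss_curve, r2$loss_curve)
  expect_length(r1$loss_curve, 3)
  log_lines <- readLines(log_path)
  expect_length(log_lines, 3)
  expect_equal(jsonlite::fromJSON(log_lines[2])$epoch, 2)

  expect_error(train(list(), net, cfg), class = "config_error")
  no_ts <- ds[[1]]; no_ts$ts_geometry <- NULL
  expect_error(train(list(no_ts), net, cfg), class = "config_error")
  expect_error(train(ds, net, train_config(epochs = 1, init_mode = "reactant_noise",
                                           seed = 1)),
               regexp = NA)  # fixtures carry reactant geometries
})

test_that("a short training run reduces the loss", {
  ds <- small_dataset()[1:2]
  net <- tiny_net(width = 16, n_layers = 2, seed = 33)
  cfg <- train_config(epochs = 15, batch_size = 4, lr = 3e-3, seed = 7, n_draws = 2)
  res <- train(ds, net, cfg)
  expect_lt(min(res$loss_curve), res$loss_curve[1])
})

test_that("cfm loss is invariant under a global rotation of the pair", {
  net <- tiny_net(seed = 34)
  rxn <- small_dataset()[[4]]
  cgr <- cgr_graph(rxn)
  set.seed(18)
  p <- flow_pair(rxn, 0.6, sample_base(rxn, "gaussian"), cgr)
  R <- random_rotation()
  p_rot <- p
  p_rot$x0 <- p$x0 %*% R; p_rot$x1 <- p$x1 %*% R
  p_rot$x_t <- p$x_t %*% R; p_rot$v_target <- p$v_target %*% R
  expect_equal(cfm_loss(net, list(p)), cfm_loss(net, list(p_rot)),
               tolerance = 1e-10)
})
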