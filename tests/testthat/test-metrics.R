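test_that("D-MAE matches a brute-force oracle and is reflection-blind", {
  set.seed(22)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    p <- matrix(rnorm(3 * n, sd = 2), n, 3)
    q <- matrix(rnorm(3 * n, sd = 2), n, 3)
    # brute-force pair enumeration
    acc <- 0; cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      acc <- acc + abs(sqrt(sum((p[i, ] - p[j, ])^2)) - sqrt(sum((q[i, ] - q[j, ])^2)))
      cnt <- cnt + 1
    }
    expect_equal(d_mae(p, q), acc / cnt, tolerance = 1e-9)
    expect_equal(d_mae(p, q), d_mae(q, p))
  }
  p <- matrix(rnorm(12), 4, 3)
  expect_equal(d_mae(p, p), 0)
  R <- random_rotation()
  expect_lt(d_mae(sweep(p %*% R, 2, c(1, 2, 3), "+"), p), 1e-9)
  expect_lt(d_mae(p %*% diag(c(-1, 1, 1)), p), 1e-9)   # reflections preserved
  expect_error(d_mae(p, matrix(0, 3, 3)), class = "input_error")
})

test_that("hand-listed 3-atom D-MAE value", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  q <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0, 0.9, 0))
  # pairs: (1,2): |1-1.1|=0.1 ; (1,3): |1-0.9|=0.1 ; (2,3): |sqrt2 - sqrt(1.21+0.81)|
  expected <- (0.1 + 0.1 + abs(sqrt(2) - sqrt(1.21 + 0.81))) / 3
  expect_equal(d_mae(p, q), expected)
})

test_that("RMSD is zero under proper motions, positive under mirrors", {
  set.seed(23)
  p <- matrix(rnorm(15, sd = 2), 5, 3)
  R <- random_rotation()
  expect_lt(rmsd(sweep(p %*% R, 2, c(3, -1, 2), "+"), p), 1e-6)

  pair <- make_chiral_pair(seed = 5)
  expect_gt(rmsd(pair$mirror, pair$reaction$ts_geometry), 0.1)
  expect_lt(d_mae(pair$mirror, pair$reaction$ts_geometry), 1e-9)

  # optimality vs random-rotation oracle
  q <- matrix(rnorm(15, sd = 2), 5, 3)
  r_opt <- rmsd(p, q)
  pc <- center_coords(p); qc <- center_coords(q)
  r_rand <- min(vapply(1:2000, function(i) {
    sqrt(mean(rowSums((pc %*% random_rotation() - qc)^2)))
  }, 0))
  expect_lte(r_opt, r_rand + 1e-9)
})

test_that("angle error averages bonded-triplet deviations in degrees", {
  # water-like fixture: truth angle 104 deg, prediction 109 deg
  mk <- function(theta) {
    rbind(c(0, 0, 0),
          c(1, 0, 0),
          c(cos(theta * pi / 180), sin(theta * pi / 180), 0))
  }
  rxn <- parse_reaction("[O:1]([H:2])[H:3]>>[O:1][H:2].[H:3]")
  cgr <- cgr_graph(rxn)
  expect_equal(angle_error(mk(109), mk(104), cgr), 5.0, tolerance = 1e-9)
  expect_equal(angle_error(mk(104), mk(104), cgr), 0)
  # invariance under rigid motion of either argument
  R <- random_rotation()
  expect_equal(angle_error(sweep(mk(109) %*% R, 2, c(1, 1, 1), "+"), mk(104), cgr),
               5.0, tolerance = 1e-9)
  # diatomic: undefined marker
  di <- parse_reaction("[O:1][H:2]>>[O:1].[H:2]")
  expect_true(is.na(angle_error(matrix(0:5, 2, 3), matrix(0:5, 2, 3), cgr_graph(di))))
})

test_that("steric clash reproduces closed-form values", {
  two <- function(r) rbind(c(0, 0, 0), c(r, 0, 0))
  expect_equal(steric_clash(two(0.7)), 1.0)                 # 4*eps at r = sigma
  expect_equal(steric_clash(two(0.35)), 4 * 0.25 * 2^12)    # 4096 at r = sigma/2
  expect_equal(steric_clash(two(0.71)), 0)                  # beyond cutoff
  expect_equal(steric_clash(two(2.0)), 0)
  expect_true(is.infinite(steric_clash(two(0))))
  # monotone decreasing toward the cutoff
  rs <- seq(0.3, 0.7, by = 0.05)
  vals <- vapply(rs, function(r) steric_clash(two(r)), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(clash_params(epsilon = -1), class = "input_error")
})

test_that("steric clash matches brute-force recomputation on random geometries", {
  set.seed(24)
  params <- clash_params()
  for (k in 1:20) {
    n <- sample(3:7, 1)
    p <- matrix(rnorm(3 * n, sd = 0.6), n, 3)
    brute <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum((p[i, ] - p[j, ])^2))
      if (r <= params$cutoff) brute <- brute + 4 * params$epsilon * (params$sigma / r)^12
    }
    expect_equal(steric_clash(p, params), brute, tolerance = 1e-9)
  }
})

test_that("evaluate aggregates per-reaction metrics", {
  ds <- small_dataset()[1:3]
  ids <- vapply(ds, function(r) r$rxn_id, "")
  truths <- setNames(lapply(ds, function(r) r$ts_geometry), ids)
  cgrs <- setNames(lapply(ds, cgr_graph), ids)

  # identical predictions: all zeros
  rep0 <- evaluate(truths, truths, cgrs)
  expect_equal(rep0$aggregate$d_mae$mean, 0)
  expect_equal(rep0$aggregate$rmsd$mean, 0, tolerance = 1e-6)
  expect_equal(rep0$aggregate$angle_error$mean, 0)
  expect_equal(rep0$aggregate$steric_clash$mean, 0)

  # perturbed predictions: aggregate mean equals the hand mean
  set.seed(25)
  preds <- setNames(lapply(ds, function(r) {
    geometry(r$elements, r$ts_geometry$coords +
               matrix(rnorm(3 * r$n_atoms, sd = 0.1), r$n_atoms, 3))
  }), ids)
  rep1 <- evaluate(preds, truths, cgrs)
  expect_equal(rep1$aggregate$d_mae$mean, mean(rep1$per_reaction$d_mae))
  expect_true(all(rep1$per_reaction$d_mae > 0))

  # singleton set: aggregates equal that reaction's metrics
  rep_s <- evaluate(preds[1], truths[1], cgrs[1])
  expect_equal(rep_s$aggregate$rmsd$mean, rep_s$per_reaction$rmsd[1])

  expect_error(evaluate(preds[-1], truths, cgrs), class = "input_error")
})

test_that("histogram bins cover every reaction", {
  ds <- small_dataset()
  ids <- vapply(ds, function(r) r$rxn_id, "")
  truths <- setNames(lapply(ds, function(r) r$ts_geometry), ids)
  cgrs <- setNames(lapply(ds, cgr_graph), ids)
  set.seed(26)
  preds <- setNames(lapply(ds, function(r) {
    geometry(r$elements, r$ts_geometry$coords +
               matrix(rnorm(3 * r$n_atoms, sd = 0.2), r$n_atoms, 3))
  }), ids)
  rep1 <- evaluate(preds, truths, cgrs)
  h <- d_mae_histogram(rep1)
  expect_equal(sum(h$count), length(ds))
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "metrics_per_reaction.csv")))
  expect_true(file.exists(file.path(dir, "metrics_aggregate.json")))
})
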