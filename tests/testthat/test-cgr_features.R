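test_that("atom features carry dual reactant/product labels", {
  # sp3 C -> sp2 C across the reaction (alcohol dehydrogenation-like toy)
  rxn <- parse_reaction(
    "[C:1]([H:3])([H:4])([H:5])[O:2][H:6]>>[C:1]([H:3])([H:4])=[O:2].[H:5].[H:6]")
  f <- atom_features(rxn, 1)
  expect_equal(unname(f[c("el_H", "el_C", "el_N", "el_O")]), c(0, 1, 0, 0))
  expect_equal(unname(f["r_hyb_sp3"]), 1)
  expect_equal(unname(f["p_hyb_sp2"]), 1)
  expect_equal(unname(f["r_degree"]), 4)
  expect_equal(unname(f["p_degree"]), 3)

  # atom untouched by the reaction: the two halves agree
  rh <- atom_features(rxn, 3)
  r_half <- rh[grep("^r_", names(rh))]
  p_half <- rh[grep("^p_", names(rh))]
  expect_equal(unname(r_half), unname(p_half))

  # formal charge 0 -> +1 shows up in the two halves
  rxn2 <- parse_reaction("[N:1]([H:2])([H:3])[H:4]>>[N+:1]([H:2])([H:3])[H:4]")
  f2 <- atom_features(rxn2, 1)
  expect_equal(unname(f2["r_charge"]), 0)
  expect_equal(unname(f2["p_charge"]), 1)

  expect_error(atom_features(rxn, 2, elements = c("H", "C")),
               class = "feature_error")
})

test_that("bond features encode breaking, forming, and order changes", {
  rxn <- parse_reaction(
    "[C:1]([H:3])([H:4])([H:5])[O:2][H:6]>>[C:1]([H:3])([H:4])=[O:2].[H:5].[H:6]")
  # double -> single is (r_single=0, r_double? ...) here C-O goes single -> double
  f <- bond_features(rxn, 1, 2)
  expect_equal(unname(f["r_single"]), 1)
  expect_equal(unname(f["p_double"]), 1)
  # broken bond: (single, absent)
  fb <- bond_features(rxn, 2, 6)
  expect_equal(unname(fb["r_single"]), 1)
  expect_equal(unname(fb["p_absent"]), 1)
  expect_error(bond_features(rxn, 3, 4), class = "feature_error")
})

test_that("null reaction gives symmetric dual labels everywhere", {
  rxn <- parse_reaction("[C:1]([H:2])([H:3])([H:4])[H:5]>>[C:1]([H:2])([H:3])([H:4])[H:5]")
  cgr <- cgr_graph(rxn)
  expect_identical(cgr$bonds$order_r, cgr$bonds$order_p)
  for (a in seq_len(cgr$n_atoms)) {
    f <- atom_features(rxn, a)
    expect_equal(unname(f[grep("^r_", names(f))]), unname(f[grep("^p_", names(f))]))
  }
})

test_that("CGR contains every union bond and symmetric edges", {
  for (rxn in small_dataset()[1:4]) {
    cgr <- cgr_graph(rxn)
    key <- function(b) paste(pmin(b$i, b$j), pmax(b$i, b$j))
    union_keys <- union(key(rxn$reactant$bonds), key(rxn$product$bonds))
    expect_setequal(key(cgr$bonds), union_keys)
    # symmetric directed edge set
    ek <- paste(cgr$edge_index[, 1], cgr$edge_index[, 2])
    rk <- paste(cgr$edge_index[, 2], cgr$edge_index[, 1])
    expect_setequal(ek, rk)
    # uniform feature dimensions
    expect_equal(ncol(cgr$node_features), 22)
    expect_equal(ncol(cgr$bond_features), 10)
  }
})

test_that("feature matrices are permutation-covariant under map renumbering", {
  s1 <- "[C:1]([H:3])([H:4])([H:5])[O:2][H:6]>>[C:1]([H:3])([H:4])=[O:2].[H:5].[H:6]"
  # renumber maps: 1<->2, 3<->6
  s2 <- "[C:2]([H:6])([H:4])([H:5])[O:1][H:3]>>[C:2]([H:6])([H:4])=[O:1].[H:5].[H:3]"
  f1 <- cgr_graph(parse_reaction(s1))$node_features
  f2 <- cgr_graph(parse_reaction(s2))$node_features
  perm <- c(2, 1, 6, 4, 5, 3)   # row i of f2 is atom perm[i] of f1
  expect_equal(f2, f1[perm, ])
})

test_that("edge set unions radius and hop neighborhoods", {
  rxn <- small_dataset()[[1]]
  cgr <- cgr_graph(rxn)
  # all pairwise distances < 10 A -> complete graph minus diagonal
  coords <- rxn$ts_geometry$coords
  ei <- build_edge_set(cgr, coords, cutoff = 10, max_hops = 3)
  expect_equal(nrow(ei), cgr$n_atoms * (cgr$n_atoms - 1))
  expect_false(any(ei[, 1] == ei[, 2]))

  # cutoff 0 on a path graph: hop edges only, shortest-path <= 3
  path_rxn <- parse_reaction(
    "[C:1][C:2][C:3][C:4][C:5]>>[C:1][C:2][C:3][C:4].[C:5]")
  pc <- cgr_graph(path_rxn)
  coords5 <- cbind(seq(0, 6, length.out = 5), 0, 0)
  ei0 <- build_edge_set(pc, coords5, cutoff = 1e-9, max_hops = 3)
  pairs <- paste(ei0[, 1], ei0[, 2])
  expect_true("1 4" %in% pairs)     # 3 hops
  expect_false("1 5" %in% pairs)    # 4 hops in the union graph
  # brute-force BFS oracle
  expected <- which(pc$hop_distance <= 3 & pc$hop_distance > 0, arr.ind = TRUE)
  expect_equal(nrow(ei0), nrow(expected))

  # two fragments far apart with no cross bonds: no cross edges at all
  frag <- parse_reaction("[C:1][C:2].[O:3][H:4]>>[C:1].[C:2].[O:3][H:4]")
  fc <- cgr_graph(frag)
  far <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(20, 0, 0), c(21, 0, 0))
  eif <- build_edge_set(fc, far, cutoff = 10, max_hops = 3)
  cross <- (eif[, 1] <= 2) != (eif[, 2] <= 2)
  expect_false(any(cross))
})

test_that("radius edges are invariant under rigid motion", {
  rxn <- small_dataset()[[2]]
  cgr <- cgr_graph(rxn)
  coords <- rxn$ts_geometry$coords
  R <- random_rotation()
  e1 <- build_edge_set(cgr, coords, cutoff = 2.0, max_hops = 0)
  e2 <- build_edge_set(cgr, sweep(coords %*% R, 2, c(5, -1, 2), "+"),
                       cutoff = 2.0, max_hops = 0)
  expect_identical(e1, e2)
})

test_that("sinusoidal time embedding matches its closed form", {
  emb0 <- time_embedding(0, 8)
  expect_equal(emb0, rep(c(0, 1), 4))
  emb <- time_embedding(0.37, 8)
  freqs <- 10000^(-(0:3) / 4)
  expect_equal(emb[c(1, 3, 5, 7)], sin(0.37 * freqs))
  expect_equal(emb[c(2, 4, 6, 8)], cos(0.37 * freqs))
  expect_error(time_embedding(1.2, 8), class = "input_error")
})

test_that("initial embeddings differ between times only via the time summand", {
  net <- tiny_net()
  cgr <- cgr_graph(small_dataset()[[1]])
  e0 <- initial_embeddings(net, cgr, 0)
  e1 <- initial_embeddings(net, cgr, 1)
  expect_equal(dim(e0$node_states), c(cgr$n_atoms, net$config$width))
  d_emb <- time_embedding(1, net$config$width) - time_embedding(0, net$config$width)
  expect_equal(e1$node_states - e0$node_states,
               matrix(d_emb, cgr$n_atoms, net$config$width, byrow = TRUE))
  expect_equal(e1$edge_states - e0$edge_states,
               matrix(d_emb, nrow(cgr$edge_index), net$config$width, byrow = TRUE))
})
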