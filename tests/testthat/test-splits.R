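test_that("reaction core captures exactly the changed-bond atoms", {
  # single broken bond: core is its two endpoints
  r1 <- parse_reaction(
    "[C:1]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:8]>>[C:1]([H:3])([H:4])[H:5].[C:2]([H:6])([H:7])[H:8]")
  core1 <- extract_core(r1)
  expect_equal(core1$core_atoms, c(1, 2))

  # order change plus a formed bond elsewhere: union of endpoints
  r2 <- parse_reaction(
    "[C:1]([H:5])([H:6])=[C:2]([H:7])[C:3]([H:8])([H:9])[O:4][H:10]>>[C:1]([H:5])([H:6])([O:4][H:10])[C:2]([H:7])[C:3]([H:8])[H:9]")
  core2 <- extract_core(r2)
  expect_setequal(core2$core_atoms, c(1, 2, 3, 4))

  # null reaction
  r3 <- parse_reaction("[C:1]([H:2])([H:3])([H:4])[H:5]>>[C:1]([H:2])([H:3])([H:4])[H:5]")
  expect_error(extract_core(r3), class = "empty_core_error")
})

test_that("map renumberings of the same transformation share a core key", {
  s1 <- "[C:1]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:8]>>[C:1]([H:3])([H:4])[H:5].[C:2]([H:6])([H:7])[H:8]"
  s2 <- "[C:8]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:1]>>[C:8]([H:3])([H:4])[H:5].[C:2]([H:6])([H:7])[H:1]"
  expect_identical(extract_core(parse_reaction(s1))$core_key,
                   extract_core(parse_reaction(s2))$core_key)
  # but breaking C-O is a different template than breaking C-C
  s3 <- "[C:1]([H:3])([H:4])([H:5])[O:2][H:6]>>[C:1]([H:3])([H:4])[H:5].[O:2][H:6]"
  expect_false(identical(extract_core(parse_reaction(s1))$core_key,
                         extract_core(parse_reaction(s3))$core_key))
  # direction matters: forming C-C differs from breaking C-C
  s4 <- "[C:1]([H:3])([H:4])[H:5].[C:2]([H:6])([H:7])[H:8]>>[C:1]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:8]"
  expect_false(identical(extract_core(parse_reaction(s1))$core_key,
                         extract_core(parse_reaction(s4))$core_key))
})

test_that("random split honors fractions, seeds, and minimum size", {
  ids <- sprintf("r%03d", 1:100)
  s <- split_random(ids, c(0.8, 0.1, 0.1), seed = 4)
  expect_partition(s, ids)
  expect_length(s$train, 80)
  expect_length(s$val, 10)
  expect_length(s$test, 10)
  expect_identical(split_random(ids, seed = 4)$test, s$test)
  assignments <- vapply(1:5, function(k) {
    paste(split_random(ids, seed = k)$test, collapse = ",")
  }, "")
  expect_gt(length(unique(assignments)), 1)
  expect_error(split_random(ids[1:2], seed = 1), class = "split_error")
  expect_error(split_random(ids, c(0.5, 0.2, 0.2), seed = 1), class = "split_error")
})

test_that("core split keeps every template in one set", {
  ds <- make_fixture_dataset(fixture_spec(n_reactions = 20, seed = 77, n_cores = 6))
  s <- split_by_core(ds, seed = 3)
  ids <- vapply(ds, function(r) r$rxn_id, "")
  expect_partition(s, ids)
  keys <- attr(s, "core_keys")
  for (pair in list(c("train", "val"), c("train", "test"), c("val", "test"))) {
    expect_length(intersect(keys[s[[pair[1]]]], keys[s[[pair[2]]]]), 0)
  }
})

test_that("core split warns when one core dominates", {
  ds <- make_fixture_dataset(fixture_spec(n_reactions = 6, seed = 7, n_cores = 1))
  expect_warning(s <- split_by_core(ds, seed = 1), class = "split_warning")
  expect_partition(s, vapply(ds, function(r) r$rxn_id, ""))
  # all reactions share the single core -> they land in one set
  sizes <- c(length(s$train), length(s$val), length(s$test))
  expect_equal(sort(sizes), c(0, 0, 6))
})

test_that("barrier split reserves the tails and keeps train contiguous", {
  ds <- make_fixture_dataset(fixture_spec(n_reactions = 12, seed = 55, n_cores = 4))
  # overwrite barriers with known values 1..100 on a replicated set
  reactions <- lapply(1:100, function(k) {
    r <- ds[[(k - 1) %% length(ds) + 1]]
    r$rxn_id <- sprintf("b%03d", k)
    r$barrier_height <- k
    r
  })
  s <- split_by_barrier(reactions, decile = 0.10, seed = 9)
  expect_partition(s, sprintf("b%03d", 1:100))
  bh <- setNames(1:100, sprintf("b%03d", 1:100))
  expect_setequal(bh[s$train], 11:90)
  expect_lt(max(bh[s$train]), min(bh[c(s$val, s$test)][bh[c(s$val, s$test)] > 50]))
  expect_gt(min(bh[s$train]), max(bh[c(s$val, s$test)][bh[c(s$val, s$test)] <= 50]))
  # both tails pooled then halved between val and test
  expect_length(s$val, 10)
  expect_length(s$test, 10)

  no_bh <- reactions[1:5]
  no_bh[[2]]$barrier_height <- NA_real_
  err <- tryCatch(split_by_barrier(no_bh, seed = 1), condition = identity)
  expect_s3_class(err, "split_error")
  expect_match(conditionMessage(err), no_bh[[2]]$rxn_id)
})

test_that("split files round-trip through the manifest", {
  ds <- make_fixture_dataset(fixture_spec(n_reactions = 12, seed = 31, n_cores = 5))
  s <- split_by_core(ds, seed = 2)
  dir <- withr::local_tempdir()
  write_split(s, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(manifest$strategy, "core")
  expect_equal(manifest$sizes$train, length(s$train))
  expect_equal(manifest$core_statistics$n_cores, 5)
  expect_identical(readLines(file.path(dir, "test.txt")), s$test)
})
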