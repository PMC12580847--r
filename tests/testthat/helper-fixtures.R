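# Shared test assets: a small fixture dataset, a tiny field network, and
# random-rotation utilities. Everything is generated in code at load time.

fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(fixture_cache$small)) {
    fixture_cache$small <- make_fixture_dataset(
      fixture_spec(n_reactions = 8, seed = 101, n_cores = 4))
  }
  fixture_cache$small
}

tiny_net <- function(width = 16, n_layers = 2, l_max = 2, seed = 3) {
  field_net(width = width, n_layers = n_layers, l_max = l_max, n_rbf = 6,
            seed = seed)
}

# Haar-ish random proper rotation (det +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random reflection (det -1)
random_reflection <- function() {
  Q <- random_rotation()
  Q %*% diag(c(-1, 1, 1))
}

expect_partition <- function(split, ids) {
  got <- c(split$train, split$val, split$test)
  expect_setequal(got, ids)
  expect_equal(anyDuplicated(got), 0L)
}
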