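# Dataset splitting: random, reaction-core, barrier-height.

#' Extract the reaction core (template)
#'
#' The core is the set of atoms incident to any bond whose (reactant order,
#' product order) pair differs — including formed and broken bonds and
#' aromaticity changes. The `core_key` is a canonical serialization of the
#' dual-labelled subgraph induced on the core atoms (elements + dual bond
#' labels, independent of atom-map numbering), so map-renumberings of the same
#' transformation collide.
#'
#' @param reaction a `ts_reaction`.
#' @param include_h if `FALSE`, hydrogens are dropped from the core (they are
#'   kept by default: hydrogen-transfer reactions hinge on them).
#' @return a `reaction_core`: `core_atoms` (map numbers), `core_key` (string),
#'   `changed_bonds` (data frame).
#' @export
extract_core <- function(reaction, include_h = TRUE) {
  cgr <- cgr_graph(reaction)
  changed <- cgr$bonds[cgr$bonds$order_r != cgr$bonds$order_p, , drop = FALSE]
  if (nrow(changed) == 0) {
    stop_tsflow("empty_core_error", "reaction %s has no changed bond", reaction$rxn_id)
  }
  core_atoms <- sort(unique(c(changed$i, changed$j)))
  if (!include_h) {
    keep <- reaction$elements[core_atoms] != "H"
    core_atoms <- core_atoms[keep]
  }
  sub <- cgr$bonds[cgr$bonds$i %in% core_atoms & cgr$bonds$j %in% core_atoms, , drop = FALSE]
  key <- canonical_core_key(reaction$elements[core_atoms], core_atoms, sub)
  structure(list(core_atoms = core_atoms, core_key = key, changed_bonds = changed),
            class = "reaction_core")
}

# Canonical string for a dual-labelled subgraph. Bond labels are encoded as
# auxiliary colored vertices subdividing each bond, so BLISS canonization sees
# both vertex (element) and edge (dual order) colors.
canonical_core_key <- function(elements, atoms, bonds) {
  n <- length(atoms)
  global_order <- union(c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
                        sort(unique(elements)))
  el_codes <- match(elements, global_order)
  order_code <- function(o) match(o, BOND_CATEGORIES)
  nb <- nrow(bonds)
  if (nb == 0) {
    return(paste0("atoms:", paste(sort(elements), collapse = ","), "|bonds:"))
  }
  idx <- match(c(bonds$i, bonds$j), atoms)
  edge_colors <- 100L + order_code(bonds$order_r) * 10L + order_code(bonds$order_p)
  edges <- rbind(cbind(idx[seq_len(nb)], n + seq_len(nb)),
                 cbind(n + seq_len(nb), idx[nb + seq_len(nb)]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  colors <- c(el_codes, edge_colors)
  if (igraph::vcount(g) < n + nb) {
    g <- igraph::add_vertices(g, n + nb - igraph::vcount(g))
  }
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  gc <- igraph::permute(g, perm)
  colc <- integer(n + nb); colc[perm] <- colors
  el <- igraph::as_edgelist(gc)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("v:", paste(colc, collapse = ","),
         "|e:", paste(paste(el[, 1], el[, 2], sep = "-"), collapse = ","))
}

new_split <- function(train, val, test, strategy, seed, fractions) {
  structure(list(train = train, val = val, test = test, strategy = strategy,
                 seed = seed, fractions = fractions), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment (%s, seed %s): %d train / %d val / %d test>\n",
              x$strategy, x$seed, length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

check_partition <- function(split, ids) {
  all_ids <- c(split$train, split$val, split$test)
  stopifnot(setequal(all_ids, ids), !anyDuplicated(all_ids))
  split
}

#' Random split
#'
#' Shuffles reaction ids with a seeded RNG and partitions them; val and test
#' get `floor(fraction * n)` reactions each, the remainder goes to train.
#'
#' @param ids character vector of reaction ids.
#' @param fractions train/val/test fractions summing to 1 (default 0.8 / 0.1 /
#'   0.1).
#' @param seed RNG seed.
#' @return a `split_assignment`.
#' @export
split_random <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9) stop_tsflow("split_error", "fractions must sum to 1")
  n <- length(ids)
  if (n < 3) stop_tsflow("split_error", "need at least 3 reactions to split")
  with_seed(seed, {
    shuffled <- sample(ids)
    n_val <- floor(fractions[2] * n)
    n_test <- floor(fractions[3] * n)
    test <- shuffled[seq_len(n_test)]
    val <- shuffled[n_test + seq_len(n_val)]
    train <- shuffled[-(seq_len(n_test + n_val))]
    check_partition(new_split(sort(train), sort(val), sort(test),
                              "random", seed, fractions), ids)
  })
}

#' Reaction-core split
#'
#' Groups reactions by their canonical core key and assigns whole cores:
#' shuffled cores fill the test set until it reaches its fraction of
#' reactions, then the validation set, and the rest go to train. No core ever
#' spans two sets. If a single core holds more than the train fraction of the
#' data, the requested fractions are unattainable; a `split_warning` is
#' raised and the split proceeds best-effort.
#'
#' @param reactions list of `ts_reaction`.
#' @param fractions train/val/test fractions.
#' @param seed RNG seed.
#' @param include_h forwarded to [extract_core()].
#' @return a `split_assignment` with a `core_keys` attribute (id -> key).
#' @export
split_by_core <- function(reactions, fractions = c(0.8, 0.1, 0.1), seed = 1,
                          include_h = TRUE) {
  ids <- vapply(reactions, function(r) r$rxn_id, "")
  keys <- vapply(reactions, function(r) extract_core(r, include_h)$core_key, "")
  groups <- split(ids, keys)
  n <- length(ids)
  if (max(lengths(groups)) > (1 - fractions[2] - fractions[3]) * n) {
    warn_tsflow("split_warning",
                "largest core holds %d of %d reactions; requested fractions unattainable",
                max(lengths(groups)), n)
  }
  with_seed(seed, {
    ord <- sample(length(groups))
    test <- character(0); val <- character(0); train <- character(0)
    target_test <- fractions[3] * n
    target_val <- fractions[2] * n
    for (k in ord) {
      g <- groups[[k]]
      if (length(test) < target_test) test <- c(test, g)
      else if (length(val) < target_val) val <- c(val, g)
      else train <- c(train, g)
    }
    out <- check_partition(new_split(sort(train), sort(val), sort(test),
                                     "core", seed, fractions), ids)
    attr(out, "core_keys") <- setNames(keys, ids)
    out
  })
}

#' Barrier-height split
#'
#' Ranks reactions by barrier height (ties broken by reaction id); the lower
#' and upper `decile` tails are pooled and randomly halved between validation
#' and test, the middle goes to train. Train therefore spans exactly the
#' contiguous inner band of the ranked barriers.
#'
#' @param reactions list of `ts_reaction`, all carrying `barrier_height`.
#' @param decile tail fraction on each side (default 0.10).
#' @param seed RNG seed for the val/test halving.
#' @return a `split_assignment`.
#' @export
split_by_barrier <- function(reactions, decile = 0.10, seed = 1) {
  ids <- vapply(reactions, function(r) r$rxn_id, "")
  bh <- vapply(reactions, function(r) r$barrier_height, 0)
  missing <- ids[is.na(bh)]
  if (length(missing) > 0) {
    stop_tsflow("split_error", "missing barrier height for: %s",
                paste(missing, collapse = ", "))
  }
  n <- length(ids)
  if (n < 3) stop_tsflow("split_error", "need at least 3 reactions to split")
  k <- floor(decile * n)
  ord <- order(bh, ids)
  lower <- ids[ord][seq_len(k)]
  upper <- ids[ord][n + 1 - seq_len(k)]
  train <- ids[ord][setdiff(seq_len(n), c(seq_len(k), n + 1 - seq_len(k)))]
  tails <- c(lower, upper)
  with_seed(seed, {
    shuffled <- sample(tails)
    n_val <- floor(length(tails) / 2)
    val <- shuffled[seq_len(n_val)]
    test <- shuffled[-seq_len(n_val)]
    check_partition(new_split(sort(train), sort(val), sort(test),
                              "barrier", seed, c(1 - 2 * decile, decile, decile)), ids)
  })
}

#' Write split files
#'
#' Three plain-text id lists plus a JSON manifest with the strategy, seed,
#' fractions, and (for core splits) per-core cluster sizes.
#'
#' @param split a `split_assignment`.
#' @param dir output directory.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (set in c("train", "val", "test")) {
    writeLines(split[[set]], file.path(dir, paste0(set, ".txt")))
  }
  manifest <- list(strategy = split$strategy, seed = split$seed,
                   fractions = split$fractions,
                   sizes = list(train = length(split$train), val = length(split$val),
                                test = length(split$test)))
  keys <- attr(split, "core_keys")
  if (!is.null(keys)) {
    sizes <- sort(table(keys), decreasing = TRUE)
    manifest$core_statistics <- list(
      n_cores = length(sizes),
      n_singletons = sum(sizes == 1),
      cluster_sizes = as.integer(sizes)
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
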