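# Condensed graph of reaction (CGR) and featurization.
#
# Reactant and product graphs are superimposed into one graph whose atoms and
# bonds carry dual labels: the state before and after the reaction. Node
# features concatenate an element one-hot with six graph-perceived properties
# (aromaticity, formal charge, hybridization, number of bonds, degree, ring
# membership) computed once on the reactant side and once on the product side.
# Bond features are the dual bond-order categories, "absent" included.

DEFAULT_ELEMENTS <- c("H", "C", "N", "O")
HYBRIDIZATIONS <- c("s", "sp", "sp2", "sp3")
BOND_CATEGORIES <- c("absent", "single", "double", "triple", "aromatic")

# Per-atom properties perceived from one side's molecular graph.
# Hybridization uses the standard count heuristic: H -> s; any triple bond or
# two doubles -> sp; any double or aromatic bond -> sp2; otherwise sp3.
perceive_side <- function(elements, charges, bonds, aromatic_atoms) {
  nn <- length(elements)
  degree <- integer(nn)
  nbonds <- numeric(nn)
  ndouble <- integer(nn); ntriple <- integer(nn); narom <- integer(nn)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      for (a in c(bonds$i[k], bonds$j[k])) {
        degree[a] <- degree[a] + 1L
        nbonds[a] <- nbonds[a] + BOND_VALENCE[[bonds$order[k]]]
        if (bonds$order[k] == "double") ndouble[a] <- ndouble[a] + 1L
        if (bonds$order[k] == "triple") ntriple[a] <- ntriple[a] + 1L
        if (bonds$order[k] == "aromatic") narom[a] <- narom[a] + 1L
      }
    }
  }
  hyb <- vapply(seq_len(nn), function(a) {
    if (elements[a] == "H") "s"
    else if (ntriple[a] > 0 || ndouble[a] >= 2) "sp"
    else if (ndouble[a] > 0 || narom[a] > 0) "sp2"
    else "sp3"
  }, "")
  in_ring <- logical(nn)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
    if (igraph::vcount(g) < nn) g <- igraph::add_vertices(g, nn - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    for (k in ring_edges) in_ring[c(bonds$i[k], bonds$j[k])] <- TRUE
  }
  arom <- aromatic_atoms | (narom > 0)
  list(aromatic = arom, charge = charges, hybridization = hyb,
       nbonds = nbonds, degree = degree, in_ring = in_ring)
}

one_hot <- function(value, levels) as.numeric(levels == value)

side_feature_vector <- function(p, a) {
  c(aromatic = as.numeric(p$aromatic[a]),
    charge = as.numeric(p$charge[a]),
    setNames(one_hot(p$hybridization[a], HYBRIDIZATIONS),
             paste0("hyb_", HYBRIDIZATIONS)),
    nbonds = p$nbonds[a],
    degree = as.numeric(p$degree[a]),
    in_ring = as.numeric(p$in_ring[a]))
}

#' Dual-labelled atom feature vector
#'
#' Concatenates the element one-hot with the six perceived atomic properties
#' (aromaticity, formal charge, hybridization one-hot, number of bonds,
#' degree, ring membership), computed on the reactant side and again on the
#' product side. For an atom untouched by the reaction the two halves are
#' identical.
#'
#' @param reaction a `ts_reaction`.
#' @param atom_map_no atom-map number (1..N).
#' @param elements supported element palette (one-hot basis); an element
#'   outside the palette raises a `feature_error`.
#' @return a named numeric vector.
#' @export
atom_features <- function(reaction, atom_map_no, elements = DEFAULT_ELEMENTS) {
  a <- atom_map_no
  if (a < 1 || a > reaction$n_atoms) {
    stop_tsflow("input_error", "atom map %d outside 1..%d", a, reaction$n_atoms)
  }
  el <- reaction$elements[a]
  if (!el %in% elements) {
    stop_tsflow("feature_error", "element %s not in supported palette {%s}",
                el, paste(elements, collapse = ","))
  }
  pr <- perceive_side(reaction$elements, reaction$reactant$charges,
                      reaction$reactant$bonds, reaction$reactant$aromatic)
  pp <- perceive_side(reaction$elements, reaction$product$charges,
                      reaction$product$bonds, reaction$product$aromatic)
  c(setNames(one_hot(el, elements), paste0("el_", elements)),
    setNames(side_feature_vector(pr, a), paste0("r_", names(side_feature_vector(pr, a)))),
    setNames(side_feature_vector(pp, a), paste0("p_", names(side_feature_vector(pp, a)))))
}

bond_order_between <- function(bonds, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  hit <- which(bonds$i == lo & bonds$j == hi)
  if (length(hit) == 0) "absent" else bonds$order[hit[1]]
}

#' Dual bond-order feature vector
#'
#' One-hot of the reactant-side bond-order category concatenated with the
#' product-side category, each over `{absent, single, double, triple,
#' aromatic}`. A breaking bond is `(order, absent)`, a forming bond
#' `(absent, order)`.
#'
#' @param reaction a `ts_reaction`.
#' @param i,j atom-map numbers; the pair must be bonded on at least one side.
#' @return a named numeric vector of length 10.
#' @export
bond_features <- function(reaction, i, j) {
  or <- bond_order_between(reaction$reactant$bonds, i, j)
  op <- bond_order_between(reaction$product$bonds, i, j)
  if (or == "absent" && op == "absent") {
    stop_tsflow("feature_error", "atoms %d and %d bonded in neither reactant nor product", i, j)
  }
  c(setNames(one_hot(or, BOND_CATEGORIES), paste0("r_", BOND_CATEGORIES)),
    setNames(one_hot(op, BOND_CATEGORIES), paste0("p_", BOND_CATEGORIES)))
}

#' Build the condensed graph of reaction
#'
#' Superimposes the reactant and product graphs. The union bond set (a bond on
#' either side) defines the CGR connectivity; every atom and bond carries dual
#' before/after labels via [atom_features()] and [bond_features()].
#'
#' @param reaction a `ts_reaction`.
#' @param elements element palette for the one-hot basis.
#' @return an object of class `cgr_graph` with `n_atoms`, `node_features`
#'   (`N x F_a` matrix), `bonds` (union bond table with `order_r`, `order_p`),
#'   `bond_features` (`B x F_b`), the symmetric directed `edge_index` over
#'   union bonds, and the all-pairs `hop_distance` matrix in the union graph.
#' @export
cgr_graph <- function(reaction, elements = DEFAULT_ELEMENTS) {
  nn <- reaction$n_atoms
  rb <- reaction$reactant$bonds
  pb <- reaction$product$bonds
  key <- function(b) paste(b$i, b$j, sep = "-")
  all_keys <- union(key(rb), key(pb))
  pairs <- do.call(rbind, lapply(strsplit(all_keys, "-"), as.integer))
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  ord <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  union_bonds <- data.frame(
    i = pairs[, 1], j = pairs[, 2],
    order_r = vapply(seq_len(nrow(pairs)),
                     function(k) bond_order_between(rb, pairs[k, 1], pairs[k, 2]), ""),
    order_p = vapply(seq_len(nrow(pairs)),
                     function(k) bond_order_between(pb, pairs[k, 1], pairs[k, 2]), ""),
    stringsAsFactors = FALSE
  )
  node_feat <- t(vapply(seq_len(nn), function(a) atom_features(reaction, a, elements),
                        numeric(length(elements) + 18L)))
  bf <- if (nrow(union_bonds) > 0) {
    t(vapply(seq_len(nrow(union_bonds)),
             function(k) bond_features(reaction, union_bonds$i[k], union_bonds$j[k]),
             numeric(10L)))
  } else matrix(0, 0, 10)
  edge_index <- if (nrow(union_bonds) > 0) {
    rbind(cbind(union_bonds$i, union_bonds$j), cbind(union_bonds$j, union_bonds$i))
  } else matrix(integer(0), 0, 2)
  hop <- hop_distances(nn, union_bonds)
  structure(list(
    n_atoms = nn,
    rxn_id = reaction$rxn_id,
    elements = reaction$elements,
    node_features = node_feat,
    bonds = union_bonds,
    bond_features = bf,
    edge_index = edge_index,
    hop_distance = hop
  ), class = "cgr_graph")
}

# All-pairs shortest-path hop counts in the union graph (Inf if disconnected).
hop_distances <- function(n_atoms, union_bonds) {
  if (nrow(union_bonds) == 0) {
    d <- matrix(Inf, n_atoms, n_atoms); diag(d) <- 0
    return(d)
  }
  g <- igraph::graph_from_edgelist(cbind(union_bonds$i, union_bonds$j), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  unname(igraph::distances(g))
}

#' @export
print.cgr_graph <- function(x, ...) {
  changed <- sum(x$bonds$order_r != x$bonds$order_p)
  cat(sprintf("<cgr_graph %s: %d atoms, %d union bonds (%d changed)>\n",
              x$rxn_id, x$n_atoms, nrow(x$bonds), changed))
  invisible(x)
}

#' Geometry-dependent model edge set
#'
#' The network's message-passing edges are the union of all atom pairs within
#' `cutoff` Angstrom of each other in the current flow state and all pairs
#' within `max_hops` bonds in the CGR union graph (defaults 10 Angstrom and 3
#' hops). The set is symmetric and self-edge-free, and is recomputed from the
#' current coordinates at every network call by default.
#'
#' @param cgr a `cgr_graph`.
#' @param coords `N x 3` coordinate matrix (current flow state), or `NULL` for
#'   hop edges only.
#' @param cutoff radius cutoff in Angstrom.
#' @param max_hops maximum graph distance for hop edges.
#' @return integer matrix of directed edges (both directions present).
#' @export
build_edge_set <- function(cgr, coords = NULL, cutoff = 10, max_hops = 3) {
  if (cutoff < 0) stop_tsflow("input_error", "cutoff must be positive")
  nn <- cgr$n_atoms
  keep <- matrix(FALSE, nn, nn)
  if (!is.null(coords) && cutoff > 0) {
    d <- as.matrix(dist(coords))
    keep <- keep | (d <= cutoff)
  }
  keep <- keep | (cgr$hop_distance <= max_hops)
  diag(keep) <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  idx
}

#' Sinusoidal time embedding
#'
#' Transformer-style embedding of the flow time `t` in `[0,1]`: interleaved
#' `sin(t * w_k)`, `cos(t * w_k)` over a geometric frequency ladder
#' `w_k = max_freq^(-(k-1)/(dim/2 - 1))`-scaled base frequencies. At `t = 0`
#' the vector is interleaved `0, 1, 0, 1, ...`.
#'
#' @param t scalar time in `[0, 1]`.
#' @param dim embedding dimension (even).
#' @param max_period largest period of the ladder.
#' @return numeric vector of length `dim`.
#' @export
time_embedding <- function(t, dim, max_period = 10000) {
  if (t < 0 || t > 1) stop_tsflow("input_error", "t must lie in [0,1], got %g", t)
  half <- dim %/% 2L
  freqs <- max_period^(-(seq_len(half) - 1) / half)
  ang <- t * freqs
  emb <- numeric(2L * half)
  emb[seq(1, 2 * half, by = 2)] <- sin(ang)
  emb[seq(2, 2 * half, by = 2)] <- cos(ang)
  if (dim > 2L * half) emb <- c(emb, 0)
  emb
}

#' Initial node and edge embeddings
#'
#' Learned affine projections of the CGR atom and bond features into the model
#' width, with a sinusoidal embedding of the flow time added to both the node
#' and the edge initial states.
#'
#' @param net a `field_net` (supplies the projection weights and width).
#' @param cgr a `cgr_graph`.
#' @param t flow time in `[0, 1]`.
#' @param edge_index optional model edge set (defaults to the CGR bond edges);
#'   edges that are not union bonds get the `(absent, absent)` bond category.
#' @return list with `node_states` (`N x width`) and `edge_states`
#'   (`E x width`).
#' @export
initial_embeddings <- function(net, cgr, t, edge_index = NULL) {
  if (is.null(edge_index)) edge_index <- cgr$edge_index
  temb <- time_embedding(t, net$config$width)
  ef <- edge_feature_matrix(cgr, edge_index)
  nf <- cbind(cgr$node_features,
              matrix(0, cgr$n_atoms, net$config$n_atom_feat - ncol(cgr$node_features)))
  node <- nf %*% net$params$W_node +
    matrix(net$params$b_node, cgr$n_atoms, net$config$width, byrow = TRUE) +
    matrix(temb, cgr$n_atoms, net$config$width, byrow = TRUE)
  edge <- ef %*% net$params$W_edge +
    matrix(net$params$b_edge, nrow(ef), net$config$width, byrow = TRUE) +
    matrix(temb, nrow(ef), net$config$width, byrow = TRUE)
  list(node_states = node, edge_states = edge)
}

# Dual bond-category features for an arbitrary edge set; non-bonded model
# edges (radius/hop-only pairs) take the (absent, absent) category.
edge_feature_matrix <- function(cgr, edge_index) {
  m <- nrow(edge_index)
  out <- matrix(0, m, 10)
  absent_row <- c(one_hot("absent", BOND_CATEGORIES), one_hot("absent", BOND_CATEGORIES))
  if (m == 0) return(out)
  bond_key <- paste(pmin(cgr$bonds$i, cgr$bonds$j), pmax(cgr$bonds$i, cgr$bonds$j))
  ek <- paste(pmin(edge_index[, 1], edge_index[, 2]),
              pmax(edge_index[, 1], edge_index[, 2]))
  hit <- match(ek, bond_key)
  for (k in seq_len(m)) {
    out[k, ] <- if (is.na(hit[k])) absent_row else cgr$bond_features[hit[k], ]
  }
  out
}

#' Dump a featurized CGR to JSON (debug aid)
#'
#' @param cgr a `cgr_graph`.
#' @param path output path.
#' @export
write_cgr_json <- function(cgr, path) {
  jsonlite::write_json(list(
    rxn_id = cgr$rxn_id, n_atoms = cgr$n_atoms, elements = cgr$elements,
    node_features = cgr$node_features, bonds = cgr$bonds,
    bond_features = cgr$bond_features
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
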