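# Synthetic reaction fixtures.
#
# Generates small atom-mapped toy reactions (3-7 heavy atoms from H/C/N/O,
# all hydrogens explicit and mapped) whose reactant and product differ by 1-2
# bond edits drawn from a template library, together with clash-free 3D "TS"
# geometries laid out by distance-geometry-style optimization. The geometries
# are distribution targets for exercising the generative machinery — they are
# NOT physical saddle points. Reactions sharing a template share a reaction
# core, so the core split has multi-member clusters; singleton templates
# dominate by construction.

BASE_BOND_LENGTH <- list(
  "H-H" = 0.74, "C-H" = 1.09, "N-H" = 1.01, "O-H" = 0.96,
  "C-C" = 1.52, "C-N" = 1.47, "C-O" = 1.43,
  "N-N" = 1.45, "N-O" = 1.40, "O-O" = 1.48
)
DOUBLE_SCALE <- 0.88      # double bonds ~12% shorter
PARTIAL_SCALE <- 1.25     # forming/breaking bonds are stretched in the TS
VALENCE <- c(H = 1, C = 4, N = 3, O = 2)

bond_length <- function(el_i, el_j, order) {
  key <- paste(sort(c(el_i, el_j)), collapse = "-")
  base <- BASE_BOND_LENGTH[[key]] %||% 1.5
  if (identical(order, "double")) base * DOUBLE_SCALE else base
}

# Template library. Each recipe: elements the palette must contain, a
# scaffold (heavy elements + forced bonds), and an edit applied after
# hydrogen fill. "reserve" keeps valence slots open on scaffold atoms
# (donor keeps a transferable H, acceptor keeps room for the new bond).
fixture_recipes <- function() {
  # reserve_attach: valence slots protected from heavy-atom attachment
  # reserve_fill: slots additionally left H-free (room for bonds formed in
  # the product; the reactant side is then a radical site, which is carried
  # as a feature, not an error)
  brk <- function(x, y) list(
    name = paste0("break_", x, y), needs = c(x, y),
    heavy = c(x, y), edges = data.frame(i = 1, j = 2, order = "single"),
    reserve_attach = c(0, 0), reserve_fill = c(0, 0),
    edit = function(mol) list(drop = list(c(1, 2))))
  brk_h <- function(x) list(
    name = paste0("break_", x, "H"), needs = c(x, "H"),
    heavy = x, edges = data.frame(i = integer(0), j = integer(0), order = character(0)),
    reserve_attach = 1, reserve_fill = 0,
    edit = function(mol) {
      h <- first_h_on(mol, 1)
      list(drop = list(c(1, h)))
    })
  frm <- function(x, y) list(
    name = paste0("form_", x, y), needs = c(x, y, "C"),
    heavy = c(x, "C", y),
    edges = data.frame(i = c(1, 2), j = c(2, 3), order = "single"),
    reserve_attach = c(1, 0, 1), reserve_fill = c(1, 0, 1),
    edit = function(mol) list(add = data.frame(i = 1, j = 3, order = "single")))
  htr <- function(don, acc) list(
    name = paste0("htrans_", don, acc), needs = c(don, acc, "C", "H"),
    heavy = c(don, "C", acc),
    edges = data.frame(i = c(1, 2), j = c(2, 3), order = "single"),
    reserve_attach = c(1, 0, 1), reserve_fill = c(0, 0, 1),
    edit = function(mol) {
      h <- first_h_on(mol, 1)
      list(drop = list(c(1, h)), add = data.frame(i = h, j = 3, order = "single"))
    })
  list(
    brk("C", "C"), brk("C", "O"), brk("C", "N"),
    brk_h("C"), brk_h("O"), brk_h("N"),
    frm("C", "C"), frm("C", "O"), frm("C", "N"),
    htr("C", "O"), htr("C", "N"), htr("O", "C"), htr("N", "C"),
    list(name = "double_to_single_CC", needs = "C",
         heavy = c("C", "C"),
         edges = data.frame(i = 1, j = 2, order = "double"),
         reserve_attach = c(0, 0), reserve_fill = c(0, 0),
         edit = function(mol) list(retype = data.frame(i = 1, j = 2, order = "single")))
  )
}

first_h_on <- function(mol, atom) {
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    oth <- if (b$i[k] == atom) b$j[k] else if (b$j[k] == atom) b$i[k] else NA
    if (!is.na(oth) && mol$elements[oth] == "H") return(oth)
  }
  stop_tsflow("fixture_error", "no transferable hydrogen on atom %d", atom)
}

#' Fixture generation spec
#'
#' @param n_reactions number of reactions.
#' @param heavy_range min/max heavy atoms per reactant (default 3-7, the RDB7
#'   regime).
#' @param elements element palette.
#' @param seed master seed; the generated set is a deterministic function of
#'   the spec.
#' @param noise coordinate jitter (Angstrom, sd) added to laid-out geometries.
#' @param n_cores number of distinct reaction templates to use (<= 14, the
#'   library size). Extra reactions pile onto the first third of the
#'   templates, so at least two thirds of cores are singletons.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_reactions = 20, heavy_range = c(3, 7),
                         elements = c("H", "C", "N", "O"), seed = 1,
                         noise = 0.02, n_cores = 8) {
  recipes <- fixture_recipes()
  if (n_cores > length(recipes)) {
    stop_tsflow("fixture_error", "n_cores must be <= %d", length(recipes))
  }
  structure(list(n_reactions = as.integer(n_reactions),
                 heavy_range = as.integer(heavy_range), elements = elements,
                 seed = as.integer(seed), noise = noise,
                 n_cores = as.integer(n_cores)),
            class = "fixture_spec")
}

# Deterministic cluster sizes: every template gets one reaction; the surplus
# is spread over the first third of the templates with harmonic weights.
fixture_cluster_sizes <- function(n, k) {
  k <- min(k, n)
  sizes <- rep(1L, k)
  extra <- n - k
  if (extra > 0) {
    m <- max(1L, k %/% 3L)
    w <- 1 / seq_len(m)
    alloc <- floor(extra * w / sum(w))
    rem <- extra - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    sizes[seq_len(m)] <- sizes[seq_len(m)] + alloc
  }
  sizes
}

# Build one reactant molecule around a recipe scaffold, then hydrogen-fill.
build_fixture_molecule <- function(recipe, n_heavy, elements) {
  heavy_el <- recipe$heavy
  bonds <- recipe$edges
  pad <- function(v, n) c(v, rep(0, n - length(v)))[seq_len(n)]
  heavy_pool <- setdiff(elements, "H")
  while (length(heavy_el) < n_heavy) {
    el <- sample(heavy_pool, 1, prob = ifelse(heavy_pool == "C", 3, 1))
    # attach to a heavy atom with spare valence beyond its reservation
    used <- bond_order_sums(length(heavy_el), bonds)
    free <- VALENCE[heavy_el] - used - pad(recipe$reserve_attach, length(heavy_el))
    cand <- which(free >= 1)
    if (length(cand) == 0) break
    at <- if (length(cand) == 1) cand else sample(cand, 1)
    heavy_el <- c(heavy_el, el)
    bonds <- rbind(bonds, data.frame(i = at, j = length(heavy_el), order = "single"))
  }
  nh <- length(heavy_el)
  elements_all <- heavy_el
  used <- bond_order_sums(nh, bonds)
  fill_reserve <- pad(recipe$reserve_fill, nh)
  for (a in seq_len(nh)) {
    n_h <- max(0, floor(VALENCE[heavy_el[a]] - used[a] - fill_reserve[a]))
    if (n_h > 0) {
      for (k in seq_len(n_h)) {
        elements_all <- c(elements_all, "H")
        bonds <- rbind(bonds, data.frame(i = a, j = length(elements_all), order = "single"))
      }
    }
  }
  list(elements = elements_all, bonds = bonds, n_heavy = nh)
}

bond_order_sums <- function(n, bonds) {
  used <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    used[bonds$i[k]] <- used[bonds$i[k]] + BOND_VALENCE[[bonds$order[k]]]
    used[bonds$j[k]] <- used[bonds$j[k]] + BOND_VALENCE[[bonds$order[k]]]
  }
  used
}

apply_edit <- function(mol, edit) {
  b <- mol$bonds
  if (!is.null(edit$drop)) {
    for (pair in edit$drop) {
      hit <- which((b$i == pair[1] & b$j == pair[2]) | (b$i == pair[2] & b$j == pair[1]))
      if (length(hit) == 0) stop_tsflow("fixture_error", "edit drops a missing bond")
      b <- b[-hit[1], , drop = FALSE]
    }
  }
  if (!is.null(edit$retype)) {
    for (k in seq_len(nrow(edit$retype))) {
      hit <- which((b$i == edit$retype$i[k] & b$j == edit$retype$j[k]) |
                     (b$i == edit$retype$j[k] & b$j == edit$retype$i[k]))
      b$order[hit[1]] <- edit$retype$order[k]
    }
  }
  if (!is.null(edit$add)) b <- rbind(b, edit$add)
  rownames(b) <- NULL
  b
}

# Distance-geometry-style layout: bonded pairs pulled to target lengths,
# non-bonded pairs pushed beyond a floor. Returns NULL if the layout fails
# the clash-freedom check.
layout_geometry <- function(elements, bond_table, partial = logical(nrow(bond_table)),
                            floor_dist = 1.6, min_sep = 0.8, maxit = 300) {
  nn <- length(elements)
  targets <- vapply(seq_len(nrow(bond_table)), function(k) {
    L <- bond_length(elements[bond_table$i[k]], elements[bond_table$j[k]],
                     bond_table$order[k])
    if (partial[k]) L * PARTIAL_SCALE else L
  }, 0)
  bonded <- matrix(FALSE, nn, nn)
  for (k in seq_len(nrow(bond_table))) {
    bonded[bond_table$i[k], bond_table$j[k]] <- TRUE
    bonded[bond_table$j[k], bond_table$i[k]] <- TRUE
  }
  nb <- which(upper.tri(bonded) & !bonded, arr.ind = TRUE)
  bi <- bond_table$i; bj <- bond_table$j

  objective <- function(par) {
    x <- matrix(par, nn, 3)
    db <- sqrt(rowSums((x[bi, , drop = FALSE] - x[bj, , drop = FALSE])^2))
    f <- sum((db - targets)^2)
    if (nrow(nb) > 0) {
      dn <- sqrt(rowSums((x[nb[, 1], , drop = FALSE] - x[nb[, 2], , drop = FALSE])^2))
      f <- f + sum(pmax(0, floor_dist - dn)^2)
    }
    f
  }
  gradient <- function(par) {
    x <- matrix(par, nn, 3)
    g <- matrix(0, nn, 3)
    rel <- x[bi, , drop = FALSE] - x[bj, , drop = FALSE]
    db <- pmax(sqrt(rowSums(rel^2)), 1e-9)
    coef <- 2 * (db - targets) / db
    for (k in seq_along(bi)) {
      gk <- coef[k] * rel[k, ]
      g[bi[k], ] <- g[bi[k], ] + gk
      g[bj[k], ] <- g[bj[k], ] - gk
    }
    if (nrow(nb) > 0) {
      reln <- x[nb[, 1], , drop = FALSE] - x[nb[, 2], , drop = FALSE]
      dn <- pmax(sqrt(rowSums(reln^2)), 1e-9)
      viol <- dn < floor_dist
      if (any(viol)) {
        coefn <- -2 * (floor_dist - dn) / dn
        for (k in which(viol)) {
          gk <- coefn[k] * reln[k, ]
          g[nb[k, 1], ] <- g[nb[k, 1], ] + gk
          g[nb[k, 2], ] <- g[nb[k, 2], ] - gk
        }
      }
    }
    as.numeric(g)
  }

  for (attempt in 1:20) {
    init <- matrix(rnorm(3 * nn, sd = 0.8 + 0.1 * attempt), nn, 3)
    fit <- optim(as.numeric(init), objective, gradient, method = "BFGS",
                 control = list(maxit = maxit))
    x <- center_coords(matrix(fit$par, nn, 3))
    if (nn < 2) return(x)
    if (min(dist(x)) >= min_sep) return(x)
  }
  NULL
}

make_one_fixture <- function(recipe, n_heavy, spec, rxn_id) {
  mol <- build_fixture_molecule(recipe, n_heavy, spec$elements)
  prod_bonds <- apply_edit(mol, recipe$edit(mol))
  nn <- length(mol$elements)

  # union graph for the TS layout; changed bonds get stretched targets
  rb_key <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  pb_key <- paste(pmin(prod_bonds$i, prod_bonds$j), pmax(prod_bonds$i, prod_bonds$j))
  union_tab <- rbind(mol$bonds, prod_bonds[!pb_key %in% rb_key, , drop = FALSE])
  uk <- paste(pmin(union_tab$i, union_tab$j), pmax(union_tab$i, union_tab$j))
  partial <- !(uk %in% rb_key) | !(uk %in% pb_key)

  ts <- layout_geometry(mol$elements, union_tab, partial)
  re <- layout_geometry(mol$elements, mol$bonds)
  if (is.null(ts) || is.null(re)) {
    stop_tsflow("fixture_error", "could not embed clash-free geometry for %s", rxn_id)
  }
  if (spec$noise > 0) {
    repeat {
      ts_j <- ts + matrix(rnorm(3 * nn, sd = spec$noise), nn, 3)
      if (min(dist(ts_j)) >= 0.8) { ts <- ts_j; break }
    }
  }

  rxn <- structure(list(
    rxn_id = rxn_id, n_atoms = nn, elements = mol$elements,
    reactant = list(elements = mol$elements, charges = integer(nn),
                    aromatic = logical(nn), bonds = normalize_bonds(mol$bonds)),
    product = list(elements = mol$elements, charges = integer(nn),
                   aromatic = logical(nn), bonds = normalize_bonds(prod_bonds)),
    reactant_smiles = NA_character_, product_smiles = NA_character_,
    ts_geometry = geometry(mol$elements, center_coords(ts), comment = rxn_id),
    reactant_geometry = geometry(mol$elements, center_coords(re),
                                 comment = paste(rxn_id, "reactant")),
    barrier_height = rlnorm(1, meanlog = log(30), sdlog = 0.4)
  ), class = "ts_reaction")
  rxn$reactant_smiles <- strsplit(serialize_reaction(rxn), ">>")[[1]][1]
  rxn$product_smiles <- strsplit(serialize_reaction(rxn), ">>")[[1]][2]
  rxn
}

normalize_bonds <- function(b) {
  swap <- b$i > b$j
  tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
  b <- b[order(b$i, b$j), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Generate a synthetic fixture dataset
#'
#' Deterministic given the spec: reactions with validated atom maps, reactant
#' + TS geometries (minimum interatomic distance 0.8 Angstrom, so every
#' ground-truth TS is steric-clash-free under the default clash parameters),
#' and lognormal synthetic barrier heights.
#'
#' @param spec a [fixture_spec()].
#' @return list of `ts_reaction` ordered by `rxn_id`.
#' @export
make_fixture_dataset <- function(spec = fixture_spec()) {
  needed <- unique(unlist(lapply(fixture_recipes(), `[[`, "needs")))
  if (!all(needed %in% spec$elements) && spec$n_cores > 0) {
    miss <- setdiff(unique(unlist(lapply(
      fixture_recipes()[seq_len(spec$n_cores)], `[[`, "needs"))), spec$elements)
    if (length(miss) > 0) {
      stop_tsflow("fixture_error", "palette lacks element(s) %s required by templates",
                  paste(miss, collapse = ","))
    }
  }
  recipes <- fixture_recipes()[seq_len(min(spec$n_cores, spec$n_reactions))]
  sizes <- fixture_cluster_sizes(spec$n_reactions, length(recipes))
  assignment <- rep(seq_along(recipes), times = sizes)
  lapply(seq_len(spec$n_reactions), function(r) {
    with_seed(child_seed(spec$seed, r), {
      recipe <- recipes[[assignment[r]]]
      lo <- max(spec$heavy_range[1], length(recipe$heavy))
      n_heavy <- sample(seq(lo, max(lo, spec$heavy_range[2])), 1)
      make_one_fixture(recipe, n_heavy, spec, sprintf("fx%04d", r))
    })
  })
}

#' Build a chiral test asset
#'
#' A tetrahedral carbon with four distinct substituents and its mirror image:
#' interatomic distances are preserved under reflection (so the distance MAE
#' between the two is zero) while no proper rotation superimposes them (so
#' the Kabsch RMSD is strictly positive) — the chirality failure mode that
#' distance-based metrics cannot see.
#'
#' @param seed orientation seed.
#' @return list with `reaction` (TS geometry attached) and `mirror` (the
#'   reflected `ts_geometry`).
#' @export
make_chiral_pair <- function(seed = 1) {
  with_seed(seed, {
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    lengths <- c(1.52, 1.47, 1.43, 1.09)     # C, N, O, H substituents
    coords <- rbind(c(0, 0, 0), dirs * lengths)
    R <- kabsch_rotation(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
    coords <- center_coords(coords %*% R)
    elements <- c("C", "C", "N", "O", "H")
    bonds <- data.frame(i = 1, j = 2:5, order = "single")
    rxn <- structure(list(
      rxn_id = "chiral0001", n_atoms = 5L, elements = elements,
      reactant = list(elements = elements, charges = integer(5),
                      aromatic = logical(5), bonds = bonds),
      product = list(elements = elements, charges = integer(5),
                     aromatic = logical(5), bonds = bonds[-1, , drop = FALSE]),
      reactant_smiles = NA_character_, product_smiles = NA_character_,
      ts_geometry = geometry(elements, coords, "chiral fixture"),
      reactant_geometry = NULL, barrier_height = 25
    ), class = "ts_reaction")
    mirror <- geometry(elements, center_coords(coords %*% diag(c(-1, 1, 1))),
                       "chiral fixture mirror")
    list(reaction = rxn, mirror = mirror)
  })
}
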