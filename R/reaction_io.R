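# Reaction and geometry I/O.
#
# Reactions come in as atom-mapped SMILES "reactant>>product" where every atom
# (hydrogens included) carries an atom-map number; map numbers must form a
# permutation of 1..N identical in elements on both sides. The atom-map number
# is the single row-order convention for every coordinate array in the package.

BOND_ORDERS <- c("single", "double", "triple", "aromatic")
BOND_VALENCE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# ---- SMILES parsing ---------------------------------------------------------

# Parse one molecule SMILES (possibly dot-disconnected) into atoms + bonds.
# Supported dialect: bracket atoms [<iso><El><@><Hn><charge>:<map>], the
# organic-subset bare atoms, aromatic c/n/o, bond symbols - = # :, branches,
# ring closures (incl. %nn), and "." separators. Stereo marks are ignored.
parse_smiles_mol <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  elements <- character(0); maps <- integer(0); charges <- integer(0)
  aromatic <- logical(0); hcount <- integer(0)
  bi <- integer(0); bj <- integer(0); border <- character(0)
  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer(0)
  ring <- list()   # closure label -> list(atom, order)

  add_atom <- function(el, map, chg, arom, hc) {
    elements[[length(elements) + 1L]] <<- el
    maps[[length(maps) + 1L]] <<- map
    charges[[length(charges) + 1L]] <<- chg
    aromatic[[length(aromatic) + 1L]] <<- arom
    hcount[[length(hcount) + 1L]] <<- hc
    length(elements)
  }
  add_bond <- function(a, b, ord) {
    if (is.na(ord)) ord <- if (aromatic[a] && aromatic[b]) "aromatic" else "single"
    bi[[length(bi) + 1L]] <<- a; bj[[length(bj) + 1L]] <<- b
    border[[length(border) + 1L]] <<- ord
  }
  connect <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NA_character_
    prev <<- idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop_tsflow("parse_error", "unclosed bracket atom in SMILES '%s'", s)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?(\\+{1,2}|-{1,2}|\\+[0-9]+|-[0-9]+)?(:([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0) stop_tsflow("parse_error", "cannot parse bracket atom [%s]", body)
      el <- m[3]
      arom <- el %in% c("c", "n", "o", "s", "p")
      if (arom) el <- toupper(el)
      hc <- if (m[5] == "") 0L else if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
      chg <- if (m[6] == "") 0L else {
        cs <- m[6]
        sign <- if (startsWith(cs, "+")) 1L else -1L
        digits <- gsub("[+-]", "", cs)
        if (digits == "") sign * nchar(cs) else sign * as.integer(digits)
      }
      map <- if (m[8] == "") NA_integer_ else as.integer(m[8])
      idx <- add_atom(el, map, chg, arom, hc)
      connect(idx)
      i <- j + 1L
    } else if (grepl("[A-Z]", ch)) {
      el <- ch
      if (i < n && grepl("[a-z]", chars[i + 1L]) &&
          paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
        el <- paste0(ch, chars[i + 1L]); i <- i + 1L
      }
      idx <- add_atom(el, NA_integer_, 0L, FALSE, 0L)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      idx <- add_atom(toupper(ch), NA_integer_, 0L, TRUE, 0L)
      connect(idx)
      i <- i + 1L
    } else if (ch == "-") { pending <- "single"; i <- i + 1L
    } else if (ch == "=") { pending <- "double"; i <- i + 1L
    } else if (ch == "#") { pending <- "triple"; i <- i + 1L
    } else if (ch == ":") { pending <- "aromatic"; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop_tsflow("parse_error", "unbalanced ')' in SMILES '%s'", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") { prev <- NA_integer_; pending <- NA_character_; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        lab <- paste(chars[(i + 1L):(i + 2L)], collapse = ""); i <- i + 3L
      } else { lab <- ch; i <- i + 1L }
      if (is.na(prev)) stop_tsflow("parse_error", "ring closure before any atom in '%s'", s)
      if (!is.null(ring[[lab]])) {
        open <- ring[[lab]]
        ord <- if (!is.na(pending)) pending else open$order
        add_bond(open$atom, prev, ord)
        ring[[lab]] <- NULL
      } else {
        ring[[lab]] <- list(atom = prev, order = pending)
      }
      pending <- NA_character_
    } else if (ch %in% c("/", "\\")) {
      pending <- "single"; i <- i + 1L   # cis/trans marks read as single bonds
    } else {
      stop_tsflow("parse_error", "unsupported SMILES character '%s' in '%s'", ch, s)
    }
  }
  if (length(ring) > 0) stop_tsflow("parse_error", "unclosed ring bond in '%s'", s)
  if (length(elements) == 0) stop_tsflow("parse_error", "empty SMILES")

  # Expand bracket H counts into explicit hydrogen atoms (unmapped; reaction
  # validation will reject them, since RDB7-style inputs map every hydrogen).
  for (a in seq_along(hcount)) {
    if (hcount[a] > 0L) {
      for (k in seq_len(hcount[a])) {
        idx <- add_atom("H", NA_integer_, 0L, FALSE, 0L)
        add_bond(a, idx, "single")
      }
    }
  }

  list(
    elements = unlist(elements), maps = unlist(maps),
    charges = unlist(charges), aromatic = unlist(aromatic),
    bonds = data.frame(i = bi, j = bj, order = border, stringsAsFactors = FALSE)
  )
}

# Reindex a parsed molecule so that atom index == atom-map number.
reorder_by_map <- function(mol, side, smiles) {
  if (anyNA(mol$maps)) {
    stop_tsflow("mapping_error", "unmapped atom(s) on %s side of '%s'", side, smiles)
  }
  nn <- length(mol$maps)
  if (!setequal(mol$maps, seq_len(nn)) || anyDuplicated(mol$maps)) {
    stop_tsflow("mapping_error",
                "atom maps on %s side are not a permutation of 1..%d", side, nn)
  }
  pos <- integer(nn); pos[mol$maps] <- seq_len(nn)   # pos[map] = old index
  b <- mol$bonds
  b$i <- mol$maps[b$i]; b$j <- mol$maps[b$j]
  swap <- b$i > b$j
  tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
  b <- b[order(b$i, b$j), , drop = FALSE]
  rownames(b) <- NULL
  list(
    elements = mol$elements[pos], charges = mol$charges[pos],
    aromatic = mol$aromatic[pos], bonds = b
  )
}

#' Parse an atom-mapped reaction SMILES
#'
#' Parses `"reactant>>product"` where every atom on both sides carries an
#' atom-map number. Hydrogens are explicit graph nodes; the map numbers must be
#' a permutation of `1..N`, identical in element at each map number on both
#' sides (bonding and formal charge may change). All coordinate arrays in the
#' package order atom rows by ascending map number.
#'
#' @param smiles_pair reaction SMILES string `"R>>P"`.
#' @param rxn_id optional reaction identifier stored on the result.
#' @param barrier_height optional activation energy in kcal/mol.
#' @return An object of class `ts_reaction` with fields `n_atoms`, `elements`
#'   (indexed by map number), per-side `reactant`/`product` bond tables and
#'   formal charges, and slots for `ts_geometry`, `reactant_geometry`,
#'   `barrier_height`.
#' @examples
#' rxn <- parse_reaction("[H:3][C:1]([H:4])=[O:2]>>[H:3][C:1]([H:4])[O:2]")
#' rxn$n_atoms
#' @export
parse_reaction <- function(smiles_pair, rxn_id = NULL, barrier_height = NULL) {
  sides <- strsplit(smiles_pair, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop_tsflow("parse_error", "reaction SMILES must contain exactly one '>>'")
  }
  r <- reorder_by_map(parse_smiles_mol(sides[1]), "reactant", smiles_pair)
  p <- reorder_by_map(parse_smiles_mol(sides[2]), "product", smiles_pair)
  if (length(r$elements) != length(p$elements)) {
    stop_tsflow("mapping_error", "reactant has %d atoms, product %d",
                length(r$elements), length(p$elements))
  }
  bad <- which(r$elements != p$elements)
  if (length(bad) > 0) {
    stop_tsflow("mapping_error",
                "element changes under map number %d (%s -> %s)",
                bad[1], r$elements[bad[1]], p$elements[bad[1]])
  }
  structure(list(
    rxn_id = rxn_id %||% NA_character_,
    n_atoms = length(r$elements),
    elements = r$elements,
    reactant = r, product = p,
    reactant_smiles = sides[1], product_smiles = sides[2],
    ts_geometry = NULL, reactant_geometry = NULL,
    barrier_height = barrier_height %||% NA_real_
  ), class = "ts_reaction")
}

#' @export
print.ts_reaction <- function(x, ...) {
  cat(sprintf("<ts_reaction %s: %d atoms, %d/%d bonds (R/P)%s%s>\n",
              x$rxn_id, x$n_atoms, nrow(x$reactant$bonds), nrow(x$product$bonds),
              if (!is.null(x$ts_geometry)) ", TS geometry" else "",
              if (!is.na(x$barrier_height)) sprintf(", barrier %.1f kcal/mol", x$barrier_height) else ""))
  invisible(x)
}

# ---- SMILES serialization ---------------------------------------------------

bond_symbol <- c(single = "-", double = "=", triple = "#", aromatic = ":")

serialize_side <- function(elements, charges, bonds) {
  nn <- length(elements)
  nb <- nrow(bonds)
  adj <- vector("list", nn)
  if (nb > 0) {
    for (k in seq_len(nb)) {
      adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], k)
      adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], k)
    }
  }
  other <- function(k, a) if (bonds$i[k] == a) bonds$j[k] else bonds$i[k]

  # pass 1: DFS spanning forest; non-tree bonds become ring closures
  visited <- logical(nn)
  tree <- logical(max(1, nb))
  classify <- function(a) {
    visited[a] <<- TRUE
    for (k in adj[[a]]) {
      b <- other(k, a)
      if (!visited[b]) { tree[k] <<- TRUE; classify(b) }
    }
  }
  for (a in seq_len(nn)) if (!visited[a]) classify(a)
  ring_bonds <- if (nb > 0) which(!tree[seq_len(nb)]) else integer(0)
  ring_label <- setNames(seq_along(ring_bonds), ring_bonds)
  lab_str <- function(l) if (l < 10) as.character(l) else sprintf("%%%02d", l)

  atom_token <- function(a) {
    chg <- charges[a]
    cs <- if (chg == 0) "" else if (chg == 1) "+" else if (chg == -1) "-" else
      sprintf("%+d", chg)
    sprintf("[%s%s:%d]", elements[a], cs, a)
  }

  # pass 2: emit along the same DFS; ring digits appear at both endpoints
  visited <- logical(nn)
  emit <- function(a) {
    visited[a] <<- TRUE
    out <- atom_token(a)
    for (k in adj[[a]]) {
      if (nb > 0 && !tree[k]) {
        out <- paste0(out, bond_symbol[[bonds$order[k]]],
                      lab_str(ring_label[[as.character(k)]]))
      }
    }
    branches <- character(0)
    for (k in adj[[a]]) {
      b <- other(k, a)
      if (nb > 0 && tree[k] && !visited[b]) {
        branches <- c(branches, paste0(bond_symbol[[bonds$order[k]]], emit(b)))
      }
    }
    if (length(branches) > 1) {
      out <- paste0(out, paste0("(", branches[-length(branches)], ")", collapse = ""),
                    branches[length(branches)])
    } else if (length(branches) == 1) {
      out <- paste0(out, branches)
    }
    out
  }

  comps <- character(0)
  for (a in seq_len(nn)) {
    if (!visited[a]) comps <- c(comps, emit(a))
  }
  paste(comps, collapse = ".")
}

#' Serialize a reaction back to atom-mapped SMILES
#'
#' The output uses bracket atoms with explicit map numbers and explicit bond
#' symbols; reparsing it yields a reaction graph-isomorphic to the input (same
#' map numbers, elements, charges, and bond multiset).
#'
#' @param reaction a `ts_reaction`.
#' @return a reaction SMILES string `"R>>P"`.
#' @export
serialize_reaction <- function(reaction) {
  paste0(
    serialize_side(reaction$elements, reaction$reactant$charges, reaction$reactant$bonds),
    ">>",
    serialize_side(reaction$elements, reaction$product$charges, reaction$product$bonds)
  )
}

#' Serialize a reaction record to JSON
#'
#' @param reaction a `ts_reaction`.
#' @return a JSON string with the SMILES, id, barrier height, and coordinates.
#' @export
reaction_to_json <- function(reaction) {
  rec <- list(
    rxn_id = reaction$rxn_id,
    rxn_smiles = serialize_reaction(reaction),
    barrier_height = if (is.na(reaction$barrier_height)) NULL else reaction$barrier_height,
    ts_coords = if (is.null(reaction$ts_geometry)) NULL else
      unname(apply(reaction$ts_geometry$coords, 1, as.numeric, simplify = FALSE)),
    elements = reaction$elements
  )
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
}

# ---- Geometry + XYZ ---------------------------------------------------------

#' Construct a geometry
#'
#' @param elements character vector of atomic symbols, ordered by atom-map
#'   number.
#' @param coords numeric `N x 3` matrix of Cartesian coordinates in Angstrom.
#' @param comment free-text comment (carries the reaction id in XYZ files).
#' @return an object of class `ts_geometry`.
#' @export
geometry <- function(elements, coords, comment = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 2) stop_tsflow("input_error", "geometry needs at least 2 atoms")
  if (nrow(coords) != length(elements) || ncol(coords) != 3) {
    stop_tsflow("input_error", "coords must be %d x 3", length(elements))
  }
  if (!all(is.finite(coords))) stop_tsflow("input_error", "non-finite coordinates")
  dimnames(coords) <- NULL
  structure(list(elements = as.character(elements), coords = coords,
                 comment = comment), class = "ts_geometry")
}

#' @export
print.ts_geometry <- function(x, ...) {
  cat(sprintf("<ts_geometry: %d atoms (%s)>\n", length(x$elements),
              paste(x$elements, collapse = "")))
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ dialect: first line the atom count, second line a comment,
#' then one `element x y z` line per atom (Angstrom).
#'
#' @param path file path.
#' @return a `ts_geometry`; the comment line is kept in `$comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop_tsflow("format_error", "XYZ file too short: %s", path)
  nn <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nn)) stop_tsflow("format_error", "bad atom count line in %s", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nn) {
    stop_tsflow("format_error", "XYZ claims %d atoms but lists %d (%s)",
                nn, length(body), path)
  }
  body <- body[seq_len(nn)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  if (any(vapply(toks, length, 1L) < 4)) {
    stop_tsflow("format_error", "malformed atom line in %s", path)
  }
  elements <- vapply(toks, `[[`, "", 1)
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (!all(is.finite(coords))) stop_tsflow("format_error", "non-numeric coordinates in %s", path)
  geometry(elements, coords, comment = lines[2])
}

#' Write an XYZ file
#'
#' Round-trips with [read_xyz()] to better than 1e-6 Angstrom.
#'
#' @param geom a `ts_geometry`.
#' @param path output file path.
#' @param comment comment line (defaults to the geometry's own comment).
#' @export
write_xyz <- function(geom, path, comment = NULL) {
  comment <- comment %||% geom$comment %||% ""
  comment <- gsub("[\r\n]", " ", comment)
  lines <- c(
    sprintf("%d", length(geom$elements)),
    comment,
    sprintf("%-2s %18.10f %18.10f %18.10f",
            geom$elements, geom$coords[, 1], geom$coords[, 2], geom$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- Dataset loading --------------------------------------------------------

#' Load a reaction dataset from CSV + XYZ files
#'
#' The CSV must have columns `rxn_id`, `rxn_smiles`, and optionally
#' `barrier_height`. Transition-state geometries are read from
#' `<xyz_dir>/<rxn_id>.xyz`, optional reactant geometries from
#' `<xyz_dir>/<rxn_id>.reactant.xyz`.
#'
#' @param csv_path path to the reaction table.
#' @param xyz_dir directory containing per-reaction XYZ files.
#' @param require_ts if `TRUE` (default), a missing TS geometry is an error.
#' @return a list of `ts_reaction`, deterministically ordered by `rxn_id`.
#' @export
load_dataset <- function(csv_path, xyz_dir, require_ts = TRUE) {
  tab <- read.csv(csv_path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(list())
  if (!all(c("rxn_id", "rxn_smiles") %in% names(tab))) {
    stop_tsflow("dataset_error", "CSV must have rxn_id and rxn_smiles columns")
  }
  tab <- tab[order(tab$rxn_id), , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(k) {
    id <- as.character(tab$rxn_id[k])
    bh <- if ("barrier_height" %in% names(tab)) as.numeric(tab$barrier_height[k]) else NA_real_
    rxn <- parse_reaction(tab$rxn_smiles[k], rxn_id = id, barrier_height = bh)
    ts_path <- file.path(xyz_dir, paste0(id, ".xyz"))
    if (file.exists(ts_path)) {
      g <- read_xyz(ts_path)
      validate_geometry_for(rxn, g, "TS")
      rxn$ts_geometry <- g
    } else if (require_ts) {
      stop_tsflow("dataset_error", "missing TS geometry for %s (%s)", id, ts_path)
    }
    re_path <- file.path(xyz_dir, paste0(id, ".reactant.xyz"))
    if (file.exists(re_path)) {
      g <- read_xyz(re_path)
      validate_geometry_for(rxn, g, "reactant")
      rxn$reactant_geometry <- g
    }
    rxn
  })
}

validate_geometry_for <- function(rxn, geom, what) {
  if (length(geom$elements) != rxn$n_atoms) {
    stop_tsflow("dataset_error", "%s geometry for %s has %d atoms, reaction has %d",
                what, rxn$rxn_id, length(geom$elements), rxn$n_atoms)
  }
  if (!all(geom$elements == rxn$elements)) {
    stop_tsflow("dataset_error",
                "%s geometry for %s disagrees with reaction elements (map order)",
                what, rxn$rxn_id)
  }
  invisible(TRUE)
}

#' Write a reaction dataset as CSV + XYZ files
#'
#' Inverse of [load_dataset()]; used by the fixture generator and the CLI.
#'
#' @param reactions list of `ts_reaction`.
#' @param dir output directory (created if absent).
#' @return the CSV path, invisibly.
#' @export
write_dataset <- function(reactions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    rxn_id = vapply(reactions, function(r) r$rxn_id, ""),
    rxn_smiles = vapply(reactions, serialize_reaction, ""),
    barrier_height = vapply(reactions, function(r) r$barrier_height, 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$rxn_id), , drop = FALSE]
  csv <- file.path(dir, "reactions.csv")
  write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  for (r in reactions) {
    if (!is.null(r$ts_geometry)) {
      write_xyz(r$ts_geometry, file.path(dir, paste0(r$rxn_id, ".xyz")), comment = r$rxn_id)
    }
    if (!is.null(r$reactant_geometry)) {
      write_xyz(r$reactant_geometry, file.path(dir, paste0(r$rxn_id, ".reactant.xyz")),
                comment = paste0(r$rxn_id, " reactant"))
    }
  }
  invisible(csv)
}
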