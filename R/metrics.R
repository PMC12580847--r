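# Geometry evaluation metrics: D-MAE, Kabsch RMSD, angle error, steric clash.

coords_of <- function(x) if (inherits(x, "ts_geometry")) x$coords else as.matrix(x)

#' Mean absolute error of interatomic distances (D-MAE)
#'
#' Mean over all unordered atom pairs of the absolute difference between the
#' two geometries' interatomic distances. Alignment-free: invariant under any
#' rigid motion or reflection of either input (so it cannot see chirality
#' errors).
#'
#' @param pred,truth `ts_geometry` or `N x 3` matrices in the same atom-map
#'   order.
#' @return D-MAE in Angstrom.
#' @export
d_mae <- function(pred, truth) {
  p <- coords_of(pred); q <- coords_of(truth)
  if (nrow(p) != nrow(q)) stop_tsflow("input_error", "atom count mismatch")
  if (nrow(p) < 2) stop_tsflow("input_error", "D-MAE needs at least 2 atoms")
  mean(abs(dist(p) - dist(q)))
}

#' Kabsch root-mean-square deviation
#'
#' RMSD after centroid superposition and the optimal proper rotation
#' (determinant +1). Reflections are not allowed, so the wrong enantiomer of a
#' chiral geometry scores high.
#'
#' @param pred,truth geometries in the same atom-map order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(pred, truth) {
  p <- coords_of(pred); q <- coords_of(truth)
  if (nrow(p) != nrow(q)) stop_tsflow("input_error", "atom count mismatch")
  if (nrow(p) < 1) stop_tsflow("input_error", "empty geometry")
  pa <- align(p, q)
  qc <- center_coords(q)
  sqrt(mean(rowSums((pa - qc)^2)))
}

# Bonded triplets (i, j, k): j is the apex, i-j and j-k union-graph bonds.
bonded_triplets <- function(cgr) {
  b <- cgr$bonds
  if (nrow(b) == 0) return(matrix(integer(0), 0, 3))
  nbrs <- vector("list", cgr$n_atoms)
  for (k in seq_len(nrow(b))) {
    nbrs[[b$i[k]]] <- c(nbrs[[b$i[k]]], b$j[k])
    nbrs[[b$j[k]]] <- c(nbrs[[b$j[k]]], b$i[k])
  }
  out <- list()
  for (j in seq_len(cgr$n_atoms)) {
    nb <- sort(nbrs[[j]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      out[[length(out) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

angle_at <- function(coords, i, j, k) {
  v1 <- coords[i, ] - coords[j, ]
  v2 <- coords[k, ] - coords[j, ]
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Mean absolute bond-angle error
#'
#' Mean over all bonded triplets of the CGR union graph of the absolute
#' difference between predicted and reference angles, in degrees. Returns
#' `NA` when the graph has no bonded triplet (diatomics); such reactions are
#' excluded from aggregates.
#'
#' @param pred,truth geometries in the same atom-map order.
#' @param cgr the reaction's `cgr_graph` (supplies the bonded triplets).
#' @return mean absolute angle error in degrees, or `NA`.
#' @export
angle_error <- function(pred, truth, cgr) {
  p <- coords_of(pred); q <- coords_of(truth)
  trip <- bonded_triplets(cgr)
  if (nrow(trip) == 0) return(NA_real_)
  errs <- vapply(seq_len(nrow(trip)), function(r) {
    abs(angle_at(p, trip[r, 1], trip[r, 2], trip[r, 3]) -
          angle_at(q, trip[r, 1], trip[r, 2], trip[r, 3]))
  }, 0)
  mean(errs)
}

#' Default steric-clash parameters
#'
#' Repulsion-only Lennard-Jones with `epsilon = 0.25` kcal/mol, `sigma = 0.7`
#' Angstrom, and pairs farther apart than `cutoff = 0.7` Angstrom contributing
#' zero.
#'
#' @export
clash_params <- function(epsilon = 0.25, sigma = 0.7, cutoff = 0.7) {
  if (epsilon <= 0 || sigma <= 0 || cutoff <= 0) {
    stop_tsflow("input_error", "clash parameters must be positive")
  }
  list(epsilon = epsilon, sigma = sigma, cutoff = cutoff)
}

#' Steric-clash error
#'
#' Sum over unordered atom pairs closer than the cutoff of the repulsive
#' Lennard-Jones term `4 eps (sigma / r)^12` (dispersion omitted). Zero when
#' no pair is within the cutoff; `Inf` for coincident atoms. Only distances
#' near or below the shortest bond lengths in the data register, so the score
#' flags physically implausible contacts.
#'
#' @param pred a geometry.
#' @param params a [clash_params()] list.
#' @return clash energy in kcal/mol.
#' @export
steric_clash <- function(pred, params = clash_params()) {
  p <- coords_of(pred)
  if (nrow(p) < 2) stop_tsflow("input_error", "steric clash needs at least 2 atoms")
  d <- as.numeric(dist(p))
  close <- d[d <= params$cutoff]
  if (length(close) == 0) return(0)
  if (any(close == 0)) return(Inf)
  sum(4 * params$epsilon * (params$sigma / close)^12)
}

#' Evaluate predictions against reference geometries
#'
#' @param predictions named list of geometries (names = reaction ids).
#' @param truths named list of reference geometries over the same ids.
#' @param cgrs named list of `cgr_graph` over the same ids.
#' @param params clash parameters.
#' @return a `metrics_report`: `per_reaction` data frame (one row per id with
#'   `d_mae`, `rmsd`, `angle_error`, `steric_clash`) and `aggregate` list of
#'   per-metric mean, median, and quartiles (angle errors average over defined
#'   reactions only).
#' @export
evaluate <- function(predictions, truths, cgrs, params = clash_params()) {
  ids <- names(predictions)
  if (is.null(ids) || !setequal(ids, names(truths)) || !setequal(ids, names(cgrs))) {
    stop_tsflow("input_error", "prediction/truth/cgr id sets do not match")
  }
  ids <- sort(ids)
  per <- data.frame(
    rxn_id = ids,
    d_mae = vapply(ids, function(id) d_mae(predictions[[id]], truths[[id]]), 0),
    rmsd = vapply(ids, function(id) rmsd(predictions[[id]], truths[[id]]), 0),
    angle_error = vapply(ids, function(id)
      angle_error(predictions[[id]], truths[[id]], cgrs[[id]]), 0),
    steric_clash = vapply(ids, function(id) steric_clash(predictions[[id]], params), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  agg <- lapply(c(d_mae = "d_mae", rmsd = "rmsd", angle_error = "angle_error",
                  steric_clash = "steric_clash"), function(col) {
    v <- per[[col]]
    v <- v[!is.na(v)]
    list(mean = mean(v), median = median(v),
         q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)))
  })
  structure(list(per_reaction = per, aggregate = agg), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %d reactions>\n", nrow(x$per_reaction)))
  cat(sprintf("  mean D-MAE %.4f A | RMSD %.4f A | angle %.3f deg | clash %.3f kcal/mol\n",
              x$aggregate$d_mae$mean, x$aggregate$rmsd$mean,
              x$aggregate$angle_error$mean, x$aggregate$steric_clash$mean))
  invisible(x)
}

#' D-MAE histogram data
#'
#' Bin counts for distribution plots of per-reaction D-MAE values.
#'
#' @param report a `metrics_report`.
#' @param breaks bin edges in Angstrom (last bin absorbs larger errors).
#' @return data frame with `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   reaction count.
#' @export
d_mae_histogram <- function(report, breaks = seq(0, 1, by = 0.05)) {
  v <- pmin(report$per_reaction$d_mae, max(breaks) - 1e-12)
  bin <- cut(v, breaks, include.lowest = TRUE, labels = FALSE)
  data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
             count = tabulate(bin, nbins = length(breaks) - 1L))
}

#' Write a metrics report to JSON + CSV
#'
#' @param report a `metrics_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_reaction, file.path(dir, "metrics_per_reaction.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$aggregate, file.path(dir, "metrics_aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(d_mae_histogram(report), file.path(dir, "d_mae_histogram.csv"),
            row.names = FALSE)
  invisible(dir)
}
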