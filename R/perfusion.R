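## Voxel region-growing perfusion model: each outlet's terminal vessel
## segment seeds a wavefront; wavefronts advance synchronously in the six
## orthogonal directions until every tumor voxel is claimed. The fraction of
## tumor volume claimed by an outlet is its tumor perfusion percentage (TPP).

## resample a polyline at (at most) `spacing` arc-length steps
.resample_polyline <- function(cl, spacing) {
  seg <- cl[-1L, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  pts <- list(cl[1L, ])
  for (i in seq_along(lens)) {
    n <- max(1L, ceiling(lens[i] / spacing))
    tt <- seq_len(n) / n
    pts[[length(pts) + 1L]] <- matrix(cl[i, ], n, 3L, byrow = TRUE) +
      tt %o% seg[i, ]
  }
  do.call(rbind, pts)
}

#' Extract per-outlet seed voxels from terminal vessel segments
#'
#' The centerline of each leaf branch (strictly between the final junction
#' and the outlet surface) is resampled at half a voxel edge and voxelized
#' by the point-in-cell test; the resulting voxels are that outlet's seeds.
#' Because sibling outlets share the junction point itself, only the distal
#' part of the terminal segment is used. Seeds of distinct outlets must not
#' overlap.
#'
#' @param tree a `vessel_tree`.
#' @param grid a `voxel_grid`.
#' @param distal_fraction fraction of the terminal segment's arc length,
#'   measured from the outlet end, that contributes seed points (default
#'   0.5; 1 uses the whole segment).
#' @return object of class `seed_set`: named list (by outlet id) of integer
#'   matrices of 0-based voxel indices.
#' @export
extract_seeds <- function(tree, grid, distal_fraction = 0.5) {
  stopifnot(distal_fraction > 0, distal_fraction <= 1)
  leaves <- tree_leaves(tree)
  seeds <- list()
  for (id in leaves) {
    b <- tree$branches[[as.character(id)]]
    pts <- .resample_polyline(b$centerline, grid$edge_length / 2)
    if (distal_fraction < 1) {
      d <- c(0, cumsum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                     pts[-nrow(pts), , drop = FALSE])^2))))
      pts <- pts[d >= (1 - distal_fraction) * d[length(d)], , drop = FALSE]
    }
    ijk <- point_to_voxel(grid, pts)
    ijk <- ijk[stats::complete.cases(ijk), , drop = FALSE]
    if (nrow(ijk) == 0L)
      stop("outlet ", b$outlet_id,
           ": terminal segment has no centerline points inside the grid")
    ijk <- unique(ijk)
    seeds[[as.character(b$outlet_id)]] <- ijk
  }
  lin <- unlist(lapply(seeds, function(m) voxel_linear(grid, m)))
  if (anyDuplicated(lin)) {
    dup <- lin[duplicated(lin)][1L]
    owners <- names(seeds)[vapply(seeds, function(m)
      dup %in% voxel_linear(grid, m), logical(1))]
    stop("terminal segments of outlets ", paste(owners, collapse = " and "),
         " share a seed voxel")
  }
  seeds <- seeds[order(as.integer(names(seeds)))]
  structure(seeds, class = "seed_set")
}

#' Simultaneous region growing from outlet seeds
#'
#' Synchronous multi-source breadth-first wavefront over the whole grid with
#' 6-connectivity: every iteration, each labeled front advances one voxel
#' layer in the six orthogonal directions; a voxel reached by several labels
#' in the same iteration goes to the lowest outlet id (deterministic,
#' order-independent tie rule). Growth passes through non-tumor voxels (seed
#' segments generally lie outside the mask); only tumor voxels count toward
#' TPP later. Terminates as soon as every tumor voxel is labeled.
#'
#' @param grid a `voxel_grid`.
#' @param seeds a `seed_set` from [extract_seeds()].
#' @return the grid with its `labels` array filled (0 where never reached).
#' @export
region_grow <- function(grid, seeds) {
  stopifnot(inherits(seeds, "seed_set"), length(seeds) > 0L)
  shape <- grid$shape
  labels <- grid$labels
  front_ijk <- do.call(rbind, unname(seeds))
  front_lab <- rep(as.integer(names(seeds)),
                   vapply(seeds, nrow, integer(1)))
  labels[voxel_linear(grid, front_ijk)] <- front_lab
  tumor_lin <- which(grid$tumor_mask)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (any(labels[tumor_lin] == 0L)) {
    if (nrow(front_ijk) == 0L)
      stop(sum(labels[tumor_lin] == 0L),
           " tumor voxel(s) unreachable from any seed")
    n <- nrow(front_ijk)
    cand_ijk <- front_ijk[rep(seq_len(n), 6L), , drop = FALSE] +
      offs[rep(seq_len(6L), each = n), ]
    cand_lab <- rep(front_lab, 6L)
    ok <- cand_ijk[, 1L] >= 0L & cand_ijk[, 1L] < shape[1L] &
      cand_ijk[, 2L] >= 0L & cand_ijk[, 2L] < shape[2L] &
      cand_ijk[, 3L] >= 0L & cand_ijk[, 3L] < shape[3L]
    cand_ijk <- cand_ijk[ok, , drop = FALSE]; cand_lab <- cand_lab[ok]
    lin <- voxel_linear(grid, cand_ijk)
    free <- labels[lin] == 0L
    cand_ijk <- cand_ijk[free, , drop = FALSE]
    cand_lab <- cand_lab[free]; lin <- lin[free]
    if (!length(lin)) {
      front_ijk <- front_ijk[0L, , drop = FALSE]; front_lab <- integer(0)
      next
    }
    ord <- order(lin, cand_lab)      # ties: lowest outlet id wins
    first <- !duplicated(lin[ord])
    sel <- ord[first]
    labels[lin[sel]] <- cand_lab[sel]
    front_ijk <- cand_ijk[sel, , drop = FALSE]
    front_lab <- cand_lab[sel]
  }
  grid$labels <- labels
  grid
}

#' Tumor perfusion percentages from a labeled grid
#'
#' TPP of an outlet is 100 x (tumor voxels labeled with that outlet) /
#' (all tumor voxels). TPPs are also written onto the tree's leaf branches.
#'
#' @param grid a labeled `voxel_grid` (all tumor voxels labeled).
#' @param tree the `vessel_tree` whose outlets produced the labels.
#' @return object of class `perfusion_map`: list with `tpp_by_outlet`
#'   (named percentage vector over all outlets), `tumor_volume_ml`,
#'   `perfused_ml_by_outlet`, and `tree` (with per-branch `tpp` filled).
#' @export
compute_tpp <- function(grid, tree) {
  tumor_labels <- grid$labels[grid$tumor_mask]
  n_tumor <- length(tumor_labels)
  if (n_tumor == 0L) stop("empty tumor mask: no tumor voxels to attribute")
  if (any(tumor_labels == 0L))
    stop(sum(tumor_labels == 0L), " tumor voxel(s) are unlabeled; run region_grow first")
  outlets <- tree_outlets(tree)
  counts <- setNames(numeric(length(outlets)), as.character(outlets))
  tab <- table(tumor_labels)
  counts[names(tab)] <- as.numeric(tab)
  tpp <- 100 * counts / n_tumor
  vol_ml <- grid$edge_length^3 * 1e6
  ob <- outlet_branch_ids(tree)
  for (o in names(tpp))
    tree$branches[[as.character(ob[[o]])]]$tpp <- tpp[[o]]
  structure(list(tpp_by_outlet = tpp,
                 tumor_volume_ml = n_tumor * vol_ml,
                 perfused_ml_by_outlet = counts * vol_ml,
                 tree = tree),
            class = "perfusion_map")
}

#' Build a perfusion map directly from known TPP values
#'
#' Convenience for analyses where territory shares are prescribed rather than
#' grown from a mask (e.g. replaying a published per-outlet table).
#'
#' @param tpp named percentage vector (by outlet id); must sum to 100.
#' @param tumor_volume_ml total tumor volume in ml.
#' @return a `perfusion_map` (without a tree).
#' @export
perfusion_map_from_tpp <- function(tpp, tumor_volume_ml) {
  if (abs(sum(tpp) - 100) > 1e-6)
    stop("TPP values must sum to 100% (got ", sum(tpp), ")")
  structure(list(tpp_by_outlet = tpp,
                 tumor_volume_ml = tumor_volume_ml,
                 perfused_ml_by_outlet = tpp / 100 * tumor_volume_ml,
                 tree = NULL),
            class = "perfusion_map")
}

#' Write a perfusion map as CSV
#' @param pm a `perfusion_map`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_perfusion_csv <- function(pm, path) {
  df <- data.frame(outlet_id = as.integer(names(pm$tpp_by_outlet)),
                   tpp_percent = unname(pm$tpp_by_outlet),
                   perfused_ml = unname(pm$perfused_ml_by_outlet))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
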