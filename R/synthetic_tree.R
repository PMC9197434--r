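## Synthetic hepatic arterial trees. These stand in for patient geometry so
## the whole pipeline can run and be tested without imaging data; they mimic
## the scale of a proper-hepatic-artery tree (mm-diameter vessels, 2-48
## outlets) but make no claim of anatomical branching statistics.

#' Specification for a synthetic arterial tree
#'
#' @param n_outlets number of outlets (>= 1).
#' @param depth maximum junction generations allowed (default: enough for a
#'   binary tree plus slack).
#' @param p_trifurcation probability that a split is a trifurcation rather
#'   than a bifurcation (arity > 3 is never generated).
#' @param diameter_rule `"murray"` (daughters sized by Murray's cube law,
#'   d_daughter = d_parent * arity^(-1/3)) or a fixed numeric ratio
#'   d_daughter / d_parent.
#' @param root_diameter root (proper hepatic artery) diameter, meters.
#' @param base_length mean proximal branch length, meters; lengths shrink
#'   geometrically with depth.
#' @param length_ratio per-generation branch length ratio.
#' @param segment_assignment optional named integer vector outlet id ->
#'   Couinaud segment (1..8); default assigns sorted outlets to segments in
#'   contiguous blocks.
#' @param rng_seed integer seed; generation is fully deterministic given the
#'   seed.
#' @return an object of class `synthetic_tree_spec`.
#' @export
synthetic_tree_spec <- function(n_outlets, depth = NULL, p_trifurcation = 0.15,
                                diameter_rule = "murray",
                                root_diameter = 5e-3, base_length = 30e-3,
                                length_ratio = 0.8,
                                segment_assignment = NULL, rng_seed = 1L) {
  n_outlets <- as.integer(n_outlets)
  if (n_outlets < 1L) stop("n_outlets must be >= 1")
  if (is.null(depth)) depth <- max(1L, ceiling(log2(max(n_outlets, 2L))) + 2L)
  if (n_outlets > 3L^depth)
    stop("infeasible: ", n_outlets, " outlets cannot be reached within depth ",
         depth, " with arity <= 3")
  structure(list(n_outlets = n_outlets, depth = as.integer(depth),
                 p_trifurcation = p_trifurcation,
                 diameter_rule = diameter_rule,
                 root_diameter = root_diameter, base_length = base_length,
                 length_ratio = length_ratio,
                 segment_assignment = segment_assignment,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_tree_spec")
}

## unit vector orthogonal pair spanning the plane normal to v
.orthonormal_frame <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = v)
}

#' Generate a synthetic arterial tree
#'
#' Builds a rooted tree with exactly `spec$n_outlets` leaves by repeated
#' splitting of the shallowest leaf; splits are bifurcations or (with
#' probability `p_trifurcation`) trifurcations. Branch centerlines are
#' straight polylines with mild random curvature, daughters fan out of the
#' parent direction, lengths shrink per generation, and diameters follow the
#' configured rule. Outlet ids are `1..n_outlets` assigned in order of leaf
#' creation; leaves receive their Couinaud segment from
#' `spec$segment_assignment`.
#'
#' @param spec a [synthetic_tree_spec()].
#' @return a validated `vessel_tree` with attribute `"segments"` (named
#'   integer vector outlet id -> Couinaud segment).
#' @export
generate_synthetic_tree <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tree_spec"))
  set.seed(spec$rng_seed)

  ## topology: list of nodes (id, parent, depth, arity of split)
  nodes <- list(list(id = 1L, parent = NA_integer_, depth = 0L))
  leaves <- 1L
  leaf_depth <- c(`1` = 0L)
  next_id <- 2L
  while (length(leaves) < spec$n_outlets) {
    ## split the shallowest leaf that still has depth budget
    cand <- leaves[leaf_depth[as.character(leaves)] < spec$depth]
    if (!length(cand)) stop("infeasible arity/depth combination during growth")
    target <- cand[which.min(leaf_depth[as.character(cand)])]
    need <- spec$n_outlets - length(leaves)
    arity <- if (need >= 2L && runif(1) < spec$p_trifurcation) 3L else 2L
    ## respect feasibility: remaining leaves must still be reachable
    kids <- integer(arity)
    d <- leaf_depth[[as.character(target)]] + 1L
    for (k in seq_len(arity)) {
      nodes[[length(nodes) + 1L]] <- list(id = next_id, parent = target, depth = d)
      kids[k] <- next_id
      next_id <- next_id + 1L
    }
    leaves <- c(setdiff(leaves, target), kids)
    leaf_depth <- leaf_depth[setdiff(names(leaf_depth), as.character(target))]
    leaf_depth[as.character(kids)] <- d
  }

  ids <- vapply(nodes, `[[`, integer(1), "id")
  parents <- vapply(nodes, `[[`, integer(1), "parent")
  depths <- vapply(nodes, `[[`, integer(1), "depth")
  n_children <- vapply(ids, function(i) sum(parents == i, na.rm = TRUE), integer(1))

  ## geometry: walk the topology, assigning directions, lengths, diameters
  dir_of <- list(); start_of <- list(); diam_of <- numeric(length(ids))
  names(diam_of) <- as.character(ids)
  order_bfs <- order(depths, ids)
  branches <- vector("list", length(ids))
  for (idx in order_bfs) {
    id <- ids[idx]; parent <- parents[idx]; depth <- depths[idx]
    if (is.na(parent)) {
      start <- c(0, 0, 0)
      dir <- c(1, 0, 0)
      diam <- spec$root_diameter
    } else {
      pkey <- as.character(parent)
      pb <- branches[[which(ids == parent)]]
      start <- pb$centerline[nrow(pb$centerline), ]
      pdir <- dir_of[[pkey]]
      sibs <- ids[!is.na(parents) & parents == parent]
      k <- match(id, sibs)
      arity <- length(sibs)
      frame <- .orthonormal_frame(pdir)
      ## daughters fan out around the parent direction
      phi <- 2 * pi * (k - 1) / arity + runif(1, -0.3, 0.3) +
        attr(pdir, "phi0") %||% 0
      theta <- runif(1, 0.35, 0.7)  # 20-40 deg off the parent axis
      dir <- cos(theta) * frame$e3 +
        sin(theta) * (cos(phi) * frame$e1 + sin(phi) * frame$e2)
      arity_eff <- max(2L, arity)
      diam <- if (identical(spec$diameter_rule, "murray"))
        diam_of[[pkey]] * arity_eff^(-1 / 3)
      else diam_of[[pkey]] * as.numeric(spec$diameter_rule)
    }
    len <- spec$base_length * spec$length_ratio^depth * runif(1, 0.85, 1.15)
    npts <- 5L
    s <- seq(0, len, length.out = npts)
    frame <- .orthonormal_frame(dir)
    wig <- len * 0.03
    bend <- runif(2, -1, 1) * wig
    offs <- outer(sin(pi * s / len), bend)  # gentle bow, zero at both ends
    cl <- matrix(start, npts, 3, byrow = TRUE) + s %o% dir +
      offs[, 1] %o% frame$e1 + offs[, 2] %o% frame$e2
    dir_of[[as.character(id)]] <- dir
    diam_of[[as.character(id)]] <- diam
    branches[[idx]] <- vessel_branch(id = id, parent = parent, centerline = cl,
                                     diameter = diam)
  }

  ## outlet labels 1..n in leaf id order
  leaf_ids <- sort(ids[n_children == 0L])
  for (j in seq_along(leaf_ids)) {
    pos <- which(ids == leaf_ids[j])
    branches[[pos]]$outlet_id <- j
  }

  tree <- vessel_tree(branches, root = 1L, contiguous_outlets = TRUE)

  segs <- spec$segment_assignment
  if (is.null(segs)) {
    n_seg <- min(8L, spec$n_outlets)
    segs <- setNames(as.integer(cut(seq_len(spec$n_outlets), breaks = n_seg,
                                    labels = FALSE)),
                     as.character(seq_len(spec$n_outlets)))
  }
  attr(tree, "segments") <- segs
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a
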