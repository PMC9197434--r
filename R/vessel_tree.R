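## Arterial tree data model. All lengths are meters internally; converters to
## mm only at I/O and reporting.

TISSUE_LEVELS <- c("healthy", "tumor", "unassigned")

#' Construct a vessel branch
#'
#' A branch is one vessel segment between two junctions (or between a junction
#' and an outlet), carrying a centerline polyline and a single fitted
#' diameter.
#'
#' @param id integer branch identifier (unique within a tree).
#' @param parent integer id of the parent branch, or `NA` for the root.
#' @param centerline numeric matrix (n x 3) of ordered centerline points,
#'   in meters; at least two rows, consecutive rows distinct.
#' @param diameter vessel diameter in meters (> 0).
#' @param outlet_id integer outlet label carried by leaf branches, else `NA`.
#' @param tissue tissue label: `"healthy"`, `"tumor"` or `"unassigned"`.
#' @param tpp tumor perfusion percentage in `[0, 100]`, or `NA` if not yet
#'   computed.
#' @param was_extended logical; `TRUE` if the outlet was artificially
#'   extruded to the extension target length.
#' @return an object of class `vessel_branch`.
#' @export
vessel_branch <- function(id, parent, centerline, diameter, outlet_id = NA,
                          tissue = "unassigned", tpp = NA_real_,
                          was_extended = FALSE) {
  centerline <- as.matrix(centerline)
  if (!is.numeric(centerline) || ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("branch ", id, ": centerline must be a numeric matrix with >= 2 rows and 3 columns")
  d <- rowSums((centerline[-1L, , drop = FALSE] -
                centerline[-nrow(centerline), , drop = FALSE])^2)
  if (any(d == 0))
    stop("branch ", id, ": centerline has repeated consecutive points")
  if (!is.finite(diameter) || diameter <= 0)
    stop("branch ", id, ": diameter must be > 0")
  if (!is.na(tpp) && (tpp < 0 || tpp > 100))
    stop("branch ", id, ": tpp must lie in [0, 100]")
  tissue <- match.arg(tissue, TISSUE_LEVELS)
  structure(list(
    id = as.integer(id),
    parent = if (is.na(parent)) NA_integer_ else as.integer(parent),
    centerline = unname(centerline),
    diameter = as.numeric(diameter),
    outlet_id = if (is.na(outlet_id)) NA_integer_ else as.integer(outlet_id),
    tissue = tissue,
    tpp = as.numeric(tpp),
    was_extended = isTRUE(was_extended)
  ), class = "vessel_branch")
}

#' Construct and validate a vessel tree
#'
#' @param branches list of [vessel_branch()] objects.
#' @param root integer id of the root branch (the proper-hepatic-artery
#'   trunk; the tree inlet sits at its first centerline point).
#' @param gravity unit 3-vector giving the gravity direction; the patient
#'   orientation is not part of the geometry, so it is stored on the tree
#'   (default `-z`).
#' @param contiguous_outlets if `TRUE`, additionally require outlet ids to be
#'   `1..n` (holds for freshly generated trees; truncated trees keep the
#'   original labels of their surviving outlets and fail this check).
#' @return an object of class `vessel_tree` with elements `branches` (named
#'   list keyed by id), `root`, `gravity`.
#' @export
vessel_tree <- function(branches, root, gravity = c(0, 0, -1),
                        contiguous_outlets = FALSE) {
  ids <- vapply(branches, function(b) b$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate branch ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(branches) <- as.character(ids)
  gravity <- as.numeric(gravity)
  if (length(gravity) != 3L || sum(gravity^2) == 0)
    stop("gravity must be a nonzero 3-vector")
  gravity <- gravity / sqrt(sum(gravity^2))
  tree <- structure(list(branches = branches, root = as.integer(root),
                         gravity = gravity), class = "vessel_tree")
  validate_tree(tree, contiguous_outlets = contiguous_outlets)
  tree
}

#' Validate vessel-tree invariants
#'
#' Checks that the branch graph is a rooted directed tree (single root, every
#' non-root branch has an existing parent, no cycles), that every junction is
#' a bifurcation or trifurcation, and that leaves carry unique outlet ids.
#'
#' @param tree a `vessel_tree`.
#' @param contiguous_outlets see [vessel_tree()].
#' @return `tree`, invisibly; errors on the first violated invariant.
#' @export
validate_tree <- function(tree, contiguous_outlets = FALSE) {
  br <- tree$branches
  ids <- as.integer(names(br))
  if (!(tree$root %in% ids)) stop("root branch ", tree$root, " not present")
  roots <- ids[vapply(br, function(b) is.na(b$parent), logical(1))]
  if (length(roots) != 1L)
    stop("tree must have exactly one root (found ", length(roots), ")")
  if (roots != tree$root) stop("declared root differs from the parentless branch")
  parents <- vapply(br, function(b) b$parent, integer(1))
  missing <- setdiff(parents[!is.na(parents)], ids)
  if (length(missing))
    stop("branch(es) reference missing parent id(s): ",
         paste(missing, collapse = ", "))
  ## cycle check: walking up from any branch must reach the root in <= n steps
  n <- length(ids)
  for (id in ids) {
    cur <- id; steps <- 0L
    while (!is.na(br[[as.character(cur)]]$parent)) {
      cur <- br[[as.character(cur)]]$parent
      steps <- steps + 1L
      if (steps > n) stop("cyclic topology detected starting from branch ", id)
    }
  }
  kids <- tree_children(tree)
  arity <- lengths(kids)
  bad <- names(arity)[!(arity %in% c(0L, 2L, 3L))]
  if (length(bad))
    stop("junction(s) with unsupported arity (must be 2 or 3 daughters): branch ",
         paste(bad, collapse = ", "))
  leaf_ids <- ids[arity[as.character(ids)] == 0L]
  out <- vapply(br[as.character(leaf_ids)], function(b) b$outlet_id, integer(1))
  if (anyNA(out)) stop("leaf branch(es) without outlet id: ",
                       paste(leaf_ids[is.na(out)], collapse = ", "))
  if (anyDuplicated(out)) stop("duplicate outlet ids: ",
                               paste(out[duplicated(out)], collapse = ", "))
  nonleaf_out <- vapply(br[as.character(setdiff(ids, leaf_ids))],
                        function(b) !is.na(b$outlet_id), logical(1))
  if (any(nonleaf_out))
    stop("non-leaf branch(es) carry an outlet id: ",
         paste(setdiff(ids, leaf_ids)[nonleaf_out], collapse = ", "))
  if (contiguous_outlets && !setequal(out, seq_along(out)))
    stop("outlet ids are not contiguous 1..", length(out))
  invisible(tree)
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("vessel_tree:", length(x$branches), "branches,",
      length(tree_outlets(x)), "outlets, root", x$root, "\n")
  invisible(x)
}

## children map: named list branch id -> integer vector of child ids
tree_children <- function(tree) {
  ids <- as.integer(names(tree$branches))
  parents <- vapply(tree$branches, function(b) b$parent, integer(1))
  kids <- lapply(ids, function(i) ids[!is.na(parents) & parents == i])
  names(kids) <- as.character(ids)
  kids
}

#' Leaf branch ids of a tree
#' @param tree a `vessel_tree`.
#' @return integer vector of branch ids with no daughters.
#' @export
tree_leaves <- function(tree) {
  kids <- tree_children(tree)
  as.integer(names(kids)[lengths(kids) == 0L])
}

#' Outlet ids of a tree (sorted)
#' @param tree a `vessel_tree`.
#' @return sorted integer vector of outlet labels carried by the leaves.
#' @export
tree_outlets <- function(tree) {
  sort(unname(vapply(tree$branches[as.character(tree_leaves(tree))],
                     function(b) b$outlet_id, integer(1))))
}

## outlet id -> branch id lookup
outlet_branch_ids <- function(tree) {
  leaves <- tree_leaves(tree)
  out <- vapply(tree$branches[as.character(leaves)],
                function(b) b$outlet_id, integer(1))
  setNames(leaves, as.character(out))
}

#' Junction level of each branch
#'
#' The root branch has level 0; a branch's level counts the junctions on the
#' path from the inlet to its start. Used to protect the most proximal
#' bifurcation levels from truncation.
#'
#' @param tree a `vessel_tree`.
#' @return named integer vector (by branch id).
#' @export
junction_levels <- function(tree) {
  kids <- tree_children(tree)
  lev <- setNames(rep(NA_integer_, length(tree$branches)), names(tree$branches))
  lev[as.character(tree$root)] <- 0L
  queue <- tree$root
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    for (ch in kids[[as.character(id)]]) {
      lev[as.character(ch)] <- lev[as.character(id)] + 1L
      queue <- c(queue, ch)
    }
  }
  lev
}

#' Centerline length of a branch
#'
#' Sum of Euclidean lengths of consecutive centerline segments.
#'
#' @param branch a `vessel_branch`, or a numeric (n x 3) polyline matrix.
#' @return length in meters.
#' @export
centerline_length <- function(branch) {
  cl <- if (inherits(branch, "vessel_branch")) branch$centerline else as.matrix(branch)
  seg <- cl[-1L, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]
  sum(sqrt(rowSums(seg^2)))
}

#' Extrude a short outlet branch to a target total length
#'
#' After pruning, a resulting outlet can sit closer than 5 mm to the
#' preceding junction, too short for the flow profile to develop. Such
#' outlets are artificially extruded along the direction of their terminal
#' centerline segment to a total length of (by default) 20 mm. Topology,
#' diameter, and all other branches are untouched.
#'
#' @param tree a `vessel_tree`.
#' @param branch_id id of a leaf branch.
#' @param target_length total centerline length after extension, meters
#'   (default 20 mm).
#' @return the modified `vessel_tree`; a no-op (with a warning) if the branch
#'   already reaches `target_length`.
#' @export
extend_outlet <- function(tree, branch_id, target_length = 20e-3) {
  key <- as.character(branch_id)
  if (!(key %in% names(tree$branches))) stop("no branch with id ", branch_id)
  if (!(branch_id %in% tree_leaves(tree)))
    stop("branch ", branch_id, " is not a leaf; only outlets can be extended")
  b <- tree$branches[[key]]
  len <- centerline_length(b)
  if (len >= target_length - 1e-12) {
    warning("branch ", branch_id, " already has length >= target; not extended")
    return(tree)
  }
  cl <- b$centerline
  tangent <- cl[nrow(cl), ] - cl[nrow(cl) - 1L, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  b$centerline <- rbind(cl, cl[nrow(cl), ] + tangent * (target_length - len))
  b$was_extended <- TRUE
  tree$branches[[key]] <- b
  tree
}

## ids of all branches in the subtree rooted at `id` (inclusive)
subtree_ids <- function(tree, id) {
  kids <- tree_children(tree)
  out <- integer(0); queue <- id
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    out <- c(out, cur)
    queue <- c(queue, kids[[as.character(cur)]])
  }
  out
}
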