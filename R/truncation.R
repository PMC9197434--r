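## Tumor-informed truncation of the arterial tree, in two steps:
##   step 1: collapse terminal junctions containing low-TPP outlets
##           (group label from the accumulated group TPP);
##   step 2: additionally collapse terminal junctions whose outlets perfuse
##           the same tissue type; mixed junctions are preserved; residual
##           low-TPP outlets are labeled by the tumor-flow majority rule.
## The two most proximal bifurcation levels and junctions without cutting
## space are never collapsed. Pruned outlets shorter than 5 mm are extruded
## to 20 mm so the flow profile can develop.

#' Truncation configuration
#'
#' @param tpp_threshold TPP at or below which an outlet is a pruning trigger
#'   (percent; default 1).
#' @param min_cut_space minimum centerline distance between consecutive
#'   junctions for a cut to be possible, meters. The criterion is verbal in
#'   the underlying methodology; 2 mm is this package's documented default.
#' @param short_outlet_limit pruned outlets shorter than this are extruded
#'   (meters; default 5 mm).
#' @param extension_target total length of extruded outlets (meters;
#'   default 20 mm).
#' @param protected_levels number of most-proximal junction levels that are
#'   never truncated (default 2).
#' @param tumor_flow_majority tumoral flow share above which a residual
#'   low-TPP outlet is labeled tumor (fraction; default 0.5).
#' @return object of class `truncation_config`.
#' @export
truncation_config <- function(tpp_threshold = 1, min_cut_space = 2e-3,
                              short_outlet_limit = 5e-3,
                              extension_target = 20e-3,
                              protected_levels = 2L,
                              tumor_flow_majority = 0.5) {
  stopifnot(tpp_threshold >= 0, tpp_threshold <= 100, min_cut_space > 0,
            short_outlet_limit > 0, extension_target > 0,
            protected_levels >= 0, tumor_flow_majority > 0,
            tumor_flow_majority < 1)
  structure(list(tpp_threshold = tpp_threshold, min_cut_space = min_cut_space,
                 short_outlet_limit = short_outlet_limit,
                 extension_target = extension_target,
                 protected_levels = as.integer(protected_levels),
                 tumor_flow_majority = tumor_flow_majority),
            class = "truncation_config")
}

## write TPPs from a perfusion map onto leaves and give provisional labels:
## tpp > threshold -> tumor; tpp == 0 -> healthy; 0 < tpp <= threshold ->
## unassigned (resolved by group or majority rules)
.label_leaves <- function(tree, tpp_map, threshold) {
  ob <- outlet_branch_ids(tree)
  for (o in names(ob)) {
    key <- as.character(ob[[o]])
    tpp <- unname(tpp_map$tpp_by_outlet[o])
    if (length(tpp) != 1L || is.na(tpp))
      stop("missing TPP for outlet ", o)
    tree$branches[[key]]$tpp <- tpp
    tree$branches[[key]]$tissue <-
      if (tpp > threshold) "tumor" else if (tpp == 0) "healthy" else "unassigned"
  }
  tree
}

## can the junction at the distal end of branch `id` be cut?
.cuttable <- function(tree, id, levels, cfg) {
  jl <- levels[[as.character(id)]] + 1L          # junction level
  if (jl <= cfg$protected_levels) return(FALSE)  # proximal levels protected
  centerline_length(tree$branches[[as.character(id)]]) >= cfg$min_cut_space
}

## collapse the terminal junction at the end of branch `id`: the daughters
## (all leaves) are removed and `id` becomes the resulting outlet
.collapse_junction <- function(state, id, label) {
  tree <- state$tree
  kids <- tree_children(tree)[[as.character(id)]]
  members <- sort(unique(unlist(
    state$members[as.character(vapply(tree$branches[as.character(kids)],
                                      function(b) b$outlet_id, integer(1)))])))
  tpp_sum <- sum(vapply(tree$branches[as.character(kids)],
                        function(b) b$tpp, numeric(1)))
  new_outlet <- min(members)
  b <- tree$branches[[as.character(id)]]
  b$outlet_id <- new_outlet
  b$tpp <- tpp_sum
  b$tissue <- label
  tree$branches[[as.character(id)]] <- b
  tree$branches[as.character(kids)] <- NULL
  state$tree <- tree
  ## drop member entries of the removed outlets, record the new group
  gone <- names(state$members)[vapply(state$members, function(m)
    all(m %in% members), logical(1))]
  state$members[gone] <- NULL
  state$members[[as.character(new_outlet)]] <- members
  state$new_leaves <- unique(c(setdiff(state$new_leaves, kids), id))
  state
}

## one fixpoint sweep over terminal junctions (deepest first);
## `rule` decides collapse and label from the daughter leaves
.sweep_terminal_junctions <- function(state, cfg, rule) {
  repeat {
    tree <- state$tree
    levels <- junction_levels(tree)
    kids <- tree_children(tree)
    leaves <- tree_leaves(tree)
    terminal <- names(kids)[lengths(kids) > 0L &
                            vapply(kids, function(k) all(k %in% leaves),
                                   logical(1))]
    if (!length(terminal)) break
    terminal <- terminal[order(-levels[terminal])]
    changed <- FALSE
    for (tj in terminal) {
      id <- as.integer(tj)
      ## the tree mutates inside the loop; re-check this is still terminal
      kids_now <- tree_children(state$tree)[[tj]]
      if (is.null(kids_now) || !length(kids_now)) next
      if (!all(kids_now %in% tree_leaves(state$tree))) next
      daughters <- state$tree$branches[as.character(kids_now)]
      if (anyNA(vapply(daughters, function(b) b$tpp, numeric(1))))
        stop("missing TPP on daughters of branch ", id)
      decision <- rule(daughters)
      if (is.null(decision)) next
      if (!.cuttable(state$tree, id, levels, cfg)) next
      state <- .collapse_junction(state, id, decision)
      changed <- TRUE
    }
    if (!changed) break
  }
  state
}

.init_state <- function(tree) {
  outlets <- tree_outlets(tree)
  list(tree = tree,
       members = setNames(lapply(outlets, identity), as.character(outlets)),
       new_leaves = integer(0))
}

.finish_state <- function(state, cfg, outlets_before) {
  tree <- state$tree
  extended <- integer(0)
  for (id in intersect(state$new_leaves, tree_leaves(tree))) {
    if (centerline_length(tree$branches[[as.character(id)]]) <
        cfg$short_outlet_limit) {
      tree <- extend_outlet(tree, id, cfg$extension_target)
      extended <- c(extended, tree$branches[[as.character(id)]]$outlet_id)
    }
  }
  validate_tree(tree)
  merged <- state$members[vapply(state$members, length, integer(1)) > 1L]
  labels <- vapply(tree$branches[as.character(tree_leaves(tree))],
                   function(b) b$tissue, character(1))
  names(labels) <- vapply(tree$branches[as.character(tree_leaves(tree))],
                          function(b) as.character(b$outlet_id), character(1))
  report <- structure(list(
    merged_groups = merged,
    members = state$members,
    extended_outlets = extended,
    labels_assigned = labels[order(as.integer(names(labels)))],
    outlets_before = outlets_before,
    outlets_after = length(tree_leaves(tree))), class = "truncation_report")
  list(tree = tree, report = report)
}

#' Truncation step 1: prune junctions containing low-TPP outlets
#'
#' Repeatedly collapses terminal junctions in which at least one outlet has
#' TPP at or below the threshold (outside the protected proximal levels and
#' where cutting space allows), accumulating TPP onto the resulting outlet.
#' The resulting outlet is labeled tumor if the group TPP exceeds the
#' threshold, healthy otherwise, and takes the lowest member outlet id.
#'
#' @param tree a `vessel_tree`.
#' @param tpp a `perfusion_map` covering all outlets.
#' @param cfg a [truncation_config()].
#' @return list with elements `tree` (pruned) and `report`
#'   (`truncation_report`: merged groups, member map, extended outlets,
#'   labels, outlet counts).
#' @export
prune_low_tpp <- function(tree, tpp, cfg = truncation_config()) {
  thr <- cfg$tpp_threshold
  tree <- .label_leaves(tree, tpp, thr)
  outlets_before <- length(tree_leaves(tree))
  state <- .init_state(tree)
  rule <- function(daughters) {
    tpps <- vapply(daughters, function(b) b$tpp, numeric(1))
    if (!any(tpps <= thr)) return(NULL)
    if (sum(tpps) > thr) "tumor" else "healthy"
  }
  state <- .sweep_terminal_junctions(state, cfg, rule)
  .finish_state(state, cfg, outlets_before)
}

#' Truncation step 2: merge same-tissue junctions
#'
#' Collapses terminal junctions whose outlets all perfuse the same tissue
#' type; junctions containing both tumor and healthy outlets are preserved.
#' Residual low-TPP outlets still trigger the step-1 group rule. Leaves that
#' end the sweep with TPP at or below the threshold and no tissue label are
#' labeled tumor if and only if the tumoral share of their flow exceeds the
#' majority fraction (requires flow boundary conditions), healthy otherwise.
#'
#' @param tree a `vessel_tree` whose leaves carry TPPs/labels (output of
#'   [prune_low_tpp()], with its report passed as `prior_report`).
#' @param tpp a `perfusion_map` on the original outlet set.
#' @param bc a `flow_bc` on the original outlet set (used for the majority
#'   rule); may be `NULL` if no residual low-TPP outlets remain.
#' @param cfg a [truncation_config()].
#' @param prior_report optional `truncation_report` from step 1 so that
#'   member groups accumulate across both steps.
#' @return list with elements `tree` and `report` as in [prune_low_tpp()].
#' @export
merge_same_tissue <- function(tree, tpp, bc = NULL, cfg = truncation_config(),
                              prior_report = NULL) {
  thr <- cfg$tpp_threshold
  outlets_before <- length(tree_leaves(tree))
  state <- .init_state(tree)
  if (!is.null(prior_report)) {
    keep <- names(state$members)
    state$members <- prior_report$members[keep]
  }
  rule <- function(daughters) {
    tpps <- vapply(daughters, function(b) b$tpp, numeric(1))
    tis <- vapply(daughters, function(b) b$tissue, character(1))
    if (any(tpps <= thr & tis == "unassigned"))
      return(if (sum(tpps) > thr) "tumor" else "healthy")
    if (all(tis == "healthy")) return("healthy")
    if (all(tis == "tumor")) return("tumor")
    NULL
  }
  state <- .sweep_terminal_junctions(state, cfg, rule)
  ## resolve residual unlabeled low-TPP leaves by the tumor-flow majority
  tree2 <- state$tree
  for (id in tree_leaves(tree2)) {
    b <- tree2$branches[[as.character(id)]]
    if (b$tissue != "unassigned") next
    if (is.null(bc))
      stop("flow boundary conditions required to label residual outlet ",
           b$outlet_id, " by the tumor-flow majority rule")
    mem <- as.character(state$members[[as.character(b$outlet_id)]])
    qt <- sum(bc$Q_t[mem]); qh <- sum(bc$Q_h[mem])
    if (qt + qh <= 0) stop("zero total flow for outlet ", b$outlet_id)
    tree2$branches[[as.character(id)]]$tissue <-
      if (qt / (qt + qh) > cfg$tumor_flow_majority) "tumor" else "healthy"
  }
  state$tree <- tree2
  .finish_state(state, cfg, outlets_before)
}

#' Run the full truncation to a given level
#'
#' Level 1 applies the low-TPP pruning step (Geometry-2-like tree); level 2
#' additionally merges same-tissue junctions and applies the tumor-flow
#' majority rule (Geometry-3-like tree).
#'
#' @param tree a `vessel_tree`.
#' @param tpp a `perfusion_map` on the full outlet set.
#' @param bc a `flow_bc` on the full outlet set (needed at level 2).
#' @param cfg a [truncation_config()].
#' @param level 1 or 2.
#' @return list with `tree` and cumulative `report`.
#' @export
truncate_tree <- function(tree, tpp, bc = NULL, cfg = truncation_config(),
                          level = 2L) {
  s1 <- prune_low_tpp(tree, tpp, cfg)
  if (level == 1L) return(s1)
  s2 <- merge_same_tissue(s1$tree, tpp, bc, cfg, prior_report = s1$report)
  s2$report$outlets_before <- s1$report$outlets_before
  s2$report$extended_outlets <- sort(unique(c(s1$report$extended_outlets,
                                              s2$report$extended_outlets)))
  s2
}

#' @export
print.truncation_report <- function(x, ...) {
  cat("truncation_report:", x$outlets_before, "->", x$outlets_after,
      "outlets;", length(x$merged_groups), "merged group(s);",
      length(x$extended_outlets), "extended outlet(s)\n")
  invisible(x)
}
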