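## Outlet flow boundary conditions. Healthy flow comes from scaled segmental
## liver volumes times a healthy perfusion rate constant, split symmetrically
## along the intrasegmental junctions; tumoral flow comes from the tumor
## volume times a (higher) cancerous perfusion rate constant, split by TPP.
## Total inflow then follows by mass conservation.

#' Perfusion rate constants
#'
#' @param k_h healthy-tissue perfusion rate constant, 1/min (default 0.100).
#' @param k_c cancerous-tissue perfusion rate constant, 1/min (default
#'   0.415, over four times the healthy value, reflecting the higher
#'   metabolic demand of tumor tissue).
#' @return object of class `perfusion_params`.
#' @export
perfusion_params <- function(k_h = 0.100, k_c = 0.415) {
  stopifnot(k_h > 0, k_c > 0)
  structure(list(k_h = k_h, k_c = k_c), class = "perfusion_params")
}

#' Default Couinaud segmental volume fractions
#'
#' Typical relative volumes of liver segments I-VIII as fractions of total
#' liver volume. These are a configurable assumption (literature-typical
#' round values); override via the `fractions` argument of [segment_map()].
#'
#' @return named numeric vector (segments `"1"`..`"8"`), summing to 1.
#' @export
default_segment_fractions <- function() {
  setNames(c(0.02, 0.06, 0.10, 0.16, 0.14, 0.16, 0.20, 0.16),
           as.character(1:8))
}

## outlets contained in the subtree of every branch (named list by branch id)
.subtree_outlets <- function(tree) {
  kids <- tree_children(tree)
  out <- setNames(vector("list", length(tree$branches)), names(tree$branches))
  ## process deepest-first
  lev <- junction_levels(tree)
  for (key in names(out)[order(-lev)]) {
    b <- tree$branches[[key]]
    if (!is.na(b$outlet_id)) out[[key]] <- b$outlet_id
    else out[[key]] <- sort(unlist(out[as.character(kids[[key]])]))
  }
  out
}

#' Intrasegmental branching fractions
#'
#' Assuming the flow splits symmetrically along each bi- or trifurcation
#' within a segment, the branching fraction of an outlet is the product of
#' 1/2 (or 1/3) over every junction on its root path at which two (three)
#' daughter subtrees lead to outlets of the same segment. Fractions sum to 1
#' within each segment.
#'
#' @param tree a `vessel_tree`.
#' @param outlet_segment named integer vector outlet id -> segment.
#' @return named numeric vector of branching fractions per outlet id.
#' @export
branching_fractions <- function(tree, outlet_segment) {
  sub_out <- .subtree_outlets(tree)
  kids <- tree_children(tree)
  ob <- outlet_branch_ids(tree)
  bf <- setNames(numeric(length(ob)), names(ob))
  for (o in names(ob)) {
    seg <- outlet_segment[[o]]
    seg_outlets <- as.integer(names(outlet_segment)[outlet_segment == seg])
    frac <- 1
    cur <- ob[[o]]
    repeat {
      parent <- tree$branches[[as.character(cur)]]$parent
      if (is.na(parent)) break
      sibs <- kids[[as.character(parent)]]
      n_rel <- sum(vapply(sub_out[as.character(sibs)], function(s)
        any(s %in% seg_outlets), logical(1)))
      if (n_rel >= 2L) frac <- frac / n_rel
      cur <- parent
    }
    bf[[o]] <- frac
  }
  bf
}

#' Map outlets to liver segments and segmental volumes
#'
#' @param tree a `vessel_tree`.
#' @param total_liver_volume_ml total liver volume, ml (default 1357).
#' @param fractions named segmental volume fractions (default
#'   [default_segment_fractions()], renormalized over the segments that
#'   actually appear in `outlet_segment`).
#' @param outlet_segment named integer vector outlet id -> segment; defaults
#'   to the tree's `"segments"` attribute.
#' @return object of class `segment_map` with segment volumes `V_s` (ml),
#'   per-outlet segment and branching fraction, and the total volume.
#' @export
segment_map <- function(tree, total_liver_volume_ml = 1357,
                        fractions = default_segment_fractions(),
                        outlet_segment = attr(tree, "segments")) {
  if (is.null(outlet_segment))
    stop("outlet_segment mapping required (tree has no 'segments' attribute)")
  outlets <- tree_outlets(tree)
  missing <- setdiff(as.character(outlets), names(outlet_segment))
  if (length(missing))
    stop("outlet(s) not mapped to a segment: ", paste(missing, collapse = ", "))
  outlet_segment <- outlet_segment[as.character(outlets)]
  present <- sort(unique(outlet_segment))
  fr <- fractions[as.character(present)]
  if (anyNA(fr)) stop("segment fractions missing for segment(s): ",
                      paste(present[is.na(fr)], collapse = ", "))
  fr <- fr / sum(fr)
  V_s <- fr * total_liver_volume_ml
  bf <- branching_fractions(tree, outlet_segment)
  structure(list(segment_volumes = V_s, outlet_segment = outlet_segment,
                 branching_fraction = bf,
                 total_liver_volume = total_liver_volume_ml),
            class = "segment_map")
}

#' Healthy flow contribution per outlet
#'
#' Segmental flow is segment volume times the healthy perfusion rate; it is
#' divided over the segment's outlets by the intrasegmental branching
#' fractions.
#'
#' @param seg a [segment_map()].
#' @param params a [perfusion_params()].
#' @return named numeric vector, ml/min per outlet id.
#' @export
healthy_outflows <- function(seg, params = perfusion_params()) {
  Q_s <- seg$segment_volumes * params$k_h
  q <- vapply(names(seg$outlet_segment), function(o) {
    s <- as.character(seg$outlet_segment[[o]])
    Q_s[[s]] * seg$branching_fraction[[o]]
  }, numeric(1))
  setNames(q, names(seg$outlet_segment))
}

#' Tumoral flow contribution per outlet
#'
#' Total tumoral flow is tumor volume times the cancerous perfusion rate;
#' each outlet receives its TPP share.
#'
#' @param tpp a `perfusion_map`.
#' @param params a [perfusion_params()].
#' @return list with `Q_t_by_outlet` (ml/min, named) and `Q_t` (total
#'   tumoral flow, ml/min).
#' @export
tumor_outflows <- function(tpp, params = perfusion_params()) {
  if (abs(sum(tpp$tpp_by_outlet) - 100) > 1e-6)
    stop("TPPs must sum to 100%")
  Q_t <- tpp$tumor_volume_ml * params$k_c
  list(Q_t_by_outlet = Q_t * tpp$tpp_by_outlet / 100, Q_t = Q_t)
}

#' Assemble outlet flow boundary conditions
#'
#' Per outlet, total outflow is healthy plus tumoral flow; the total inflow
#' is their sum by mass conservation.
#'
#' @param healthy named healthy flows (ml/min) from [healthy_outflows()].
#' @param tumoral result of [tumor_outflows()] (or a named vector of
#'   tumoral flows in ml/min).
#' @return object of class `flow_bc` with `Q_h`, `Q_t`, `Q_b` (named,
#'   ml/min), `Q_t_total`, `total_inflow` (ml/min) and `flow_fraction_pct`
#'   (percent of inflow per outlet).
#' @export
assemble_bc <- function(healthy, tumoral) {
  qt <- if (is.list(tumoral)) tumoral$Q_t_by_outlet else tumoral
  if (!setequal(names(healthy), names(qt)))
    stop("healthy and tumoral flows cover different outlet sets")
  qt <- qt[names(healthy)]
  if (any(healthy < 0) || any(qt < 0)) stop("negative flow encountered")
  qb <- healthy + qt
  ord <- order(as.integer(names(qb)))
  qb <- qb[ord]; healthy <- healthy[ord]; qt <- qt[ord]
  structure(list(Q_h = healthy, Q_t = qt, Q_b = qb,
                 Q_t_total = sum(qt), total_inflow = sum(qb),
                 flow_fraction_pct = 100 * qb / sum(qb)),
            class = "flow_bc")
}

#' @export
print.flow_bc <- function(x, ...) {
  cat("flow_bc:", length(x$Q_b), "outlets; healthy", round(sum(x$Q_h)),
      "+ tumoral", round(sum(x$Q_t)), "= total", round(x$total_inflow),
      "ml/min\n")
  invisible(x)
}

#' Flow fractions of truncated outlets
#'
#' For each truncated outlet, the flow fraction of a member outlet is its
#' full-tree outflow divided by the summed outflow of the group; fractions
#' sum to 1 per group. Un-truncated outlets get fraction 1.
#'
#' @param full_bc a `flow_bc` on the full outlet set.
#' @param report a `truncation_report` (its `members` map links truncated
#'   outlets to full-tree member outlets).
#' @return named list: truncated outlet id -> named numeric vector of member
#'   flow fractions.
#' @export
flow_fractions <- function(full_bc, report) {
  lapply(report$members, function(mem) {
    q <- full_bc$Q_b[as.character(mem)]
    if (anyNA(q)) stop("member outlet(s) missing from the full flow_bc: ",
                       paste(mem[is.na(q)], collapse = ", "))
    tot <- sum(q)
    if (tot <= 0) stop("truncated outlet with zero total flow (members ",
                       paste(mem, collapse = ", "), ")")
    q / tot
  })
}

#' Aggregate a full-tree flow_bc onto a truncated outlet set
#'
#' Each truncated outlet's healthy/tumoral/total flows are the sums over its
#' member outlets, so mass conservation and the total inflow are preserved
#' exactly.
#'
#' @param full_bc a `flow_bc` on the full outlet set.
#' @param report a `truncation_report`.
#' @return a `flow_bc` keyed by the truncated outlet ids.
#' @export
truncated_bc <- function(full_bc, report) {
  qh <- vapply(report$members, function(m) sum(full_bc$Q_h[as.character(m)]),
               numeric(1))
  qt <- vapply(report$members, function(m) sum(full_bc$Q_t[as.character(m)]),
               numeric(1))
  assemble_bc(qh, qt)
}

#' Write a flow-bc table as CSV
#' @param bc a `flow_bc`.
#' @param path destination CSV path.
#' @param seg optional `segment_map` to include the segment column.
#' @return `path`, invisibly.
#' @export
write_bc_csv <- function(bc, path, seg = NULL) {
  df <- data.frame(outlet_id = as.integer(names(bc$Q_b)),
                   Q_h_ml_min = unname(bc$Q_h),
                   Q_t_ml_min = unname(bc$Q_t),
                   Q_b_ml_min = unname(bc$Q_b),
                   flow_fraction_percent = unname(bc$flow_fraction_pct))
  if (!is.null(seg))
    df$segment <- unname(seg$outlet_segment[as.character(df$outlet_id)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Published reference outlet table of the full-complexity geometry
#'
#' Per-outlet diameters and imposed flow fractions of a 48-outlet hepatic
#' arterial tree, shipped as package data for reference analyses (the flow
#' fraction column sums to 100.00%).
#'
#' @return data frame with columns `outlet`, `diameter_mm`,
#'   `flow_fraction_pct`.
#' @export
geometry1_outlets <- function() {
  read.csv(system.file("extdata", "geometry1_outlets.csv",
                       package = "hepatrunc"))
}
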