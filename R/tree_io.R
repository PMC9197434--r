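## Tree JSON format. Schema (units meters):
## {"branches":[{"id","parent","centerline":[[x,y,z],...],"diameter",
##   "outlet_id","tissue_label","tpp"}],"root","gravity":[gx,gy,gz]}

#' Read a vessel tree from its JSON file format
#'
#' @param path path to a tree JSON file.
#' @return a validated `vessel_tree`.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("branches", "root", "gravity"))
    if (is.null(js[[field]])) stop("tree file missing required field '", field, "'")
  branches <- lapply(js$branches, function(bj) {
    for (field in c("id", "centerline", "diameter"))
      if (is.null(bj[[field]]))
        stop("branch entry missing required field '", field, "'")
    cl <- do.call(rbind, lapply(bj$centerline, function(p) {
      p <- as.numeric(p)
      if (length(p) != 3L) stop("branch ", bj$id, ": centerline point is not 3-D")
      p
    }))
    vessel_branch(
      id = bj$id,
      parent = if (is.null(bj$parent)) NA else bj$parent,
      centerline = cl,
      diameter = bj$diameter,
      outlet_id = if (is.null(bj$outlet_id)) NA else bj$outlet_id,
      tissue = if (is.null(bj$tissue_label)) "unassigned" else bj$tissue_label,
      tpp = if (is.null(bj$tpp)) NA_real_ else as.numeric(bj$tpp),
      was_extended = isTRUE(bj$was_extended)
    )
  })
  vessel_tree(branches, root = js$root, gravity = as.numeric(js$gravity))
}

#' Write a vessel tree to the JSON file format
#'
#' @param tree a `vessel_tree`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path) {
  branches <- lapply(tree$branches, function(b) {
    out <- list(
      id = b$id,
      parent = if (is.na(b$parent)) NULL else b$parent,
      centerline = apply(b$centerline, 1L, identity, simplify = FALSE),
      diameter = b$diameter,
      tissue_label = b$tissue,
      was_extended = b$was_extended
    )
    if (!is.na(b$outlet_id)) out$outlet_id <- b$outlet_id
    if (!is.na(b$tpp)) out$tpp <- b$tpp
    out
  })
  js <- list(branches = unname(branches), root = tree$root,
             gravity = tree$gravity)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
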