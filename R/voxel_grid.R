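## Cubic voxel grid holding the tumor mask and the perfusion-territory label
## volume. Indexing is 0-based with half-open cells
## [origin + i*h, origin + (i+1)*h); a point belongs to the voxel whose cell
## contains it.

#' Construct a voxel grid
#'
#' @param shape integer 3-vector of voxel counts per axis.
#' @param edge_length cubic voxel edge length, meters.
#' @param origin 3-D position (meters) of the grid corner (low corner of
#'   voxel `(0,0,0)`).
#' @param tumor_mask logical array of dimension `shape` marking tumor voxels;
#'   defaults to all-`FALSE`.
#' @return object of class `voxel_grid` with an integer `labels` array
#'   (0 = unlabeled) alongside the mask.
#' @export
voxel_grid <- function(shape, edge_length, origin = c(0, 0, 0),
                       tumor_mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), edge_length > 0,
            length(origin) == 3L)
  if (is.null(tumor_mask)) tumor_mask <- array(FALSE, dim = shape)
  tumor_mask <- array(as.logical(tumor_mask), dim = shape)
  structure(list(shape = shape, edge_length = as.numeric(edge_length),
                 origin = as.numeric(origin), tumor_mask = tumor_mask,
                 labels = array(0L, dim = shape)),
            class = "voxel_grid")
}

#' Fit a voxel grid around a tree and tumor geometry
#'
#' Chooses the edge length so that a cubic grid of the requested shape covers
#' the joint bounding box of the vessel centerlines and the given physical
#' box, mirroring how a 100^3 grid over a patient bounding box yields a
#' ~1.2 mm voxel.
#'
#' @param tree a `vessel_tree`.
#' @param box optional 2x3 matrix (rows: min, max corners, meters) to include.
#' @param shape voxel counts (default `c(100, 100, 100)`).
#' @param margin fractional padding added around the bounding box.
#' @return a `voxel_grid`.
#' @export
fit_voxel_grid <- function(tree, box = NULL, shape = c(100L, 100L, 100L),
                           margin = 0.05) {
  pts <- do.call(rbind, lapply(tree$branches, function(b) b$centerline))
  lo <- apply(pts, 2L, min); hi <- apply(pts, 2L, max)
  if (!is.null(box)) { lo <- pmin(lo, box[1L, ]); hi <- pmax(hi, box[2L, ]) }
  span <- hi - lo
  pad <- margin * max(span)
  lo <- lo - pad; hi <- hi + pad
  h <- max((hi - lo) / shape)
  ## center the cubic grid on the box
  center <- (lo + hi) / 2
  origin <- center - shape * h / 2
  voxel_grid(shape, h, origin)
}

## point (n x 3, meters) -> 0-based integer voxel indices (n x 3); NA outside
point_to_voxel <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3L)
  idx <- floor(sweep(sweep(pts, 2L, grid$origin), 2L, grid$edge_length, "/"))
  bad <- idx < 0 | sweep(idx, 2L, grid$shape, ">=")
  idx[rowSums(bad) > 0L, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

## 0-based (i,j,k) -> 1-based linear index into arrays of dim grid$shape
voxel_linear <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  1L + ijk[, 1L] + grid$shape[1L] * (ijk[, 2L] + grid$shape[2L] * ijk[, 3L])
}

#' Paint an ellipsoidal tumor into a voxel grid
#'
#' Marks voxels whose centers lie inside the union of the given ellipsoids.
#' Multi-lobed masks are unions of several ellipsoids.
#'
#' @param grid a `voxel_grid`.
#' @param centers matrix (k x 3) of ellipsoid centers, meters.
#' @param radii matrix (k x 3) of semi-axes, meters (recycled if one row).
#' @return the grid with `tumor_mask` set.
#' @export
add_ellipsoid_tumor <- function(grid, centers, radii) {
  centers <- matrix(centers, ncol = 3L)
  radii <- matrix(radii, ncol = 3L)
  if (nrow(radii) == 1L) radii <- radii[rep(1L, nrow(centers)), , drop = FALSE]
  h <- grid$edge_length
  ax <- grid$origin[1L] + (seq_len(grid$shape[1L]) - 0.5) * h
  ay <- grid$origin[2L] + (seq_len(grid$shape[2L]) - 0.5) * h
  az <- grid$origin[3L] + (seq_len(grid$shape[3L]) - 0.5) * h
  for (k in seq_len(nrow(centers))) {
    dx2 <- ((ax - centers[k, 1L]) / radii[k, 1L])^2
    dy2 <- ((ay - centers[k, 2L]) / radii[k, 2L])^2
    dz2 <- ((az - centers[k, 3L]) / radii[k, 3L])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    grid$tumor_mask <- grid$tumor_mask | inside
  }
  grid
}

#' Tumor volume of a grid in milliliters
#' @param grid a `voxel_grid`.
#' @return volume in ml (`n_tumor_voxels * edge_length^3 * 1e6`).
#' @export
tumor_volume_ml <- function(grid) {
  sum(grid$tumor_mask) * grid$edge_length^3 * 1e6
}

#' Read a tumor mask from a NIfTI volume
#'
#' Nonzero voxels become tumor. The voxel size is taken from the NIfTI
#' header (must be isotropic within 1%).
#'
#' @param path NIfTI file path.
#' @return a `voxel_grid`.
#' @export
read_tumor_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)[1:3] * 1e-3  # NIfTI mm -> meters
  if (diff(range(pix)) > 0.01 * mean(pix))
    stop("anisotropic voxels are not supported (pixdim: ",
         paste(signif(pix, 4), collapse = " x "), " m)")
  voxel_grid(dim(img)[1:3], mean(pix), origin = c(0, 0, 0),
             tumor_mask = img != 0)
}

#' Write the tumor mask or label volume as NIfTI
#'
#' @param grid a `voxel_grid`.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @param what `"labels"` or `"mask"`.
#' @return `path`, invisibly.
#' @export
write_grid_nifti <- function(grid, path, what = c("labels", "mask")) {
  what <- match.arg(what)
  vol <- if (what == "labels") grid$labels else array(as.integer(grid$tumor_mask),
                                                     dim = grid$shape)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(grid$edge_length * 1e3, 3L)  # meters -> NIfTI mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
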