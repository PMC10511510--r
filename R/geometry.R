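#' Volumetric image with physical geometry
#'
#' The basic container for a 3D MR volume: a numeric voxel array plus the
#' metadata needed to place every voxel in physical (scanner) space. The
#' physical position of voxel index \code{(i, j, k)} (1-based) is
#' \code{origin + orientation \%*\% (spacing * (c(i, j, k) - 1))}, in mm.
#'
#' @param voxels 3D numeric array of voxel values.
#' @param spacing numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param orientation 3x3 direction matrix mapping index axes to physical
#'   axes; must be orthonormal to within 1e-6.
#' @return An object of class \code{volumetric_image}.
#' @examples
#' img <- volumetric_image(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
#' voxel_volume_mm3(img)
#' @export
volumetric_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             orientation = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("'orientation' must be a 3x3 orthonormal matrix", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "volumetric_image")
}

#' Integer label mask on an image grid
#'
#' A mask sharing the geometry of a [volumetric_image]. Binary masks
#' (\code{kind} \code{"tumor"} or \code{"brain"}) may only contain 0/1;
#' \code{"parcellation"} masks hold arbitrary non-negative integer labels.
#'
#' @param labels 3D array of non-negative integers.
#' @param grid a \code{volumetric_image} or \code{label_mask} supplying the
#'   geometry (spacing/origin/orientation); its voxel data are ignored.
#' @param kind one of \code{"tumor"}, \code{"brain"}, \code{"parcellation"}.
#' @return An object of class \code{label_mask}.
#' @export
label_mask <- function(labels, grid, kind = c("tumor", "brain", "parcellation")) {
  kind <- match.arg(kind)
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array", call. = FALSE)
  if (!inherits(grid, c("volumetric_image", "label_mask")))
    stop("'grid' must be a volumetric_image or label_mask", call. = FALSE)
  if (!identical(dim(labels), image_shape(grid)))
    stop("mask shape ", paste(dim(labels), collapse = "x"),
         " does not match grid shape ",
         paste(image_shape(grid), collapse = "x"), call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  if (kind %in% c("tumor", "brain") && any(labels > 1))
    stop("a '", kind, "' mask must be binary (0/1)", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = geom_spacing(grid),
                 origin = geom_origin(grid),
                 orientation = geom_orientation(grid), kind = kind),
            class = "label_mask")
}

## geometry accessors work on both images and masks
#' @rdname volumetric_image
#' @param x a \code{volumetric_image} or \code{label_mask}.
#' @export
image_shape <- function(x) {
  if (inherits(x, "label_mask")) dim(x$labels) else dim(x$voxels)
}

geom_spacing <- function(x) x$spacing
geom_origin <- function(x) x$origin
geom_orientation <- function(x) x$orientation

#' @rdname volumetric_image
#' @export
voxel_volume_mm3 <- function(x) prod(geom_spacing(x))

#' Physical coordinates of voxel indices
#'
#' @param x image or mask supplying the geometry.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of physical positions in mm.
#' @export
index_to_physical <- function(x, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx - 1, 2L, geom_spacing(x), `*`) %*% t(geom_orientation(x)) +
    matrix(geom_origin(x), nrow(idx), 3L, byrow = TRUE)
}

#' @rdname index_to_physical
#' @param pts n x 3 matrix of physical positions (mm).
#' @export
physical_to_index <- function(x, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  d <- pts - matrix(geom_origin(x), nrow(pts), 3L, byrow = TRUE)
  sweep(d %*% geom_orientation(x), 2L, geom_spacing(x), `/`) + 1
}

#' Test whether two volumes share a grid
#'
#' Shape must match exactly; spacing and origin agree within \code{tol} mm
#' and the orientation matrices within \code{tol}. This mirrors the import
#' rule that an annotation must carry matching volume parameters before it
#' can be linked to an MR scan.
#'
#' @param a,b images or masks.
#' @param tol numeric tolerance (mm for spacing/origin).
#' @export
same_geometry <- function(a, b, tol = 1e-3) {
  identical(image_shape(a), image_shape(b)) &&
    max(abs(geom_spacing(a) - geom_spacing(b))) <= tol &&
    max(abs(geom_origin(a) - geom_origin(b))) <= tol &&
    max(abs(geom_orientation(a) - geom_orientation(b))) <= tol
}

stop_geometry_mismatch <- function(what) {
  stop("geometry mismatch: ", what,
       " must share shape, spacing, origin and orientation", call. = FALSE)
}

#' @export
print.volumetric_image <- function(x, ...) {
  cat("<volumetric_image> ", paste(image_shape(x), collapse = " x "),
      " voxels @ ", paste(format(x$spacing, digits = 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  origin (mm): ", paste(format(x$origin, digits = 4), collapse = ", "),
      "\n  intensity range: [",
      paste(format(range(x$voxels), digits = 4), collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask:", x$kind, "> ",
      paste(image_shape(x), collapse = " x "), " voxels @ ",
      paste(format(x$spacing, digits = 4), collapse = " x "), " mm; ",
      sum(x$labels > 0L), " foreground voxels\n", sep = "")
  invisible(x)
}
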