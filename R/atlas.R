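#' Spatial transforms between patient and reference space
#'
#' Affine (or rigid/identity) maps from a moving image's physical space
#' to a reference physical space: \code{y = matrix \%*\% x + translation}
#' (mm). Deformable registration engines can be plugged in as
#' \code{kind = "external"} by supplying forward and inverse point-mapping
#' functions; the package itself only fits affine transforms.
#'
#' @param kind \code{"identity"}, \code{"rigid"}, \code{"affine"} or
#'   \code{"external"}.
#' @param matrix 3x3 matrix (internal kinds); must be invertible.
#' @param translation length-3 translation, mm.
#' @param forward,inverse for \code{kind = "external"}: functions mapping
#'   an n x 3 matrix of physical points forward/backward.
#' @export
spatial_transform <- function(kind = c("affine", "rigid", "identity",
                                       "external"),
                              matrix = diag(3), translation = c(0, 0, 0),
                              forward = NULL, inverse = NULL) {
  kind <- match.arg(kind)
  if (kind == "external") {
    if (!is.function(forward) || !is.function(inverse))
      stop("external transforms need 'forward' and 'inverse' functions",
           call. = FALSE)
    return(structure(list(kind = kind, forward = forward, inverse = inverse),
                     class = "spatial_transform"))
  }
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  if (abs(det(matrix)) < 1e-12)
    stop("transform matrix is singular", call. = FALSE)
  structure(list(kind = kind, matrix = matrix,
                 translation = as.numeric(translation)),
            class = "spatial_transform")
}

#' @rdname spatial_transform
#' @export
identity_transform <- function() spatial_transform("identity")

#' @rdname spatial_transform
#' @param tf a \code{spatial_transform}.
#' @param pts n x 3 matrix of physical points (mm).
#' @param direction \code{"forward"} (moving to reference) or
#'   \code{"inverse"}.
#' @export
apply_transform <- function(tf, pts, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  pts <- base::matrix(as.numeric(pts), ncol = 3L)
  if (tf$kind == "external")
    return(if (direction == "forward") tf$forward(pts) else tf$inverse(pts))
  if (direction == "forward") {
    pts %*% t(tf$matrix) +
      base::matrix(tf$translation, nrow(pts), 3L, byrow = TRUE)
  } else {
    (pts - base::matrix(tf$translation, nrow(pts), 3L, byrow = TRUE)) %*%
      t(solve(tf$matrix))
  }
}

#' Atlas bundle: reference template, hemispheres, parcellations
#'
#' The reference-space bundle against which tumor features are profiled:
#' a template volume (standing in for a standard symmetric brain
#' template), a hemisphere mask (labels 1 = left, 2 = right), and one or
#' more named parcellations, each with a label table mapping every
#' nonzero label to a structure name. All masks must live on the
#' reference grid.
#'
#' @param reference [volumetric_image] template.
#' @param hemispheres [label_mask] (kind parcellation) with labels 1/2.
#' @param parcellations named list of [label_mask] objects.
#' @param label_tables named list (same names) of data.frames with
#'   columns \code{label} (integer) and \code{name}; must cover every
#'   nonzero label present.
#' @export
atlas_bundle <- function(reference, hemispheres, parcellations, label_tables) {
  if (!inherits(reference, "volumetric_image"))
    stop("'reference' must be a volumetric_image", call. = FALSE)
  if (!same_geometry(reference, hemispheres))
    stop_geometry_mismatch("hemisphere mask")
  if (!all(unique(hemispheres$labels[hemispheres$labels > 0L]) %in% 1:2))
    stop("hemisphere labels must be 1 (left) and 2 (right)", call. = FALSE)
  if (is.null(names(parcellations)) ||
      !identical(sort(names(parcellations)), sort(names(label_tables))))
    stop("'parcellations' and 'label_tables' must share names", call. = FALSE)
  for (nm in names(parcellations)) {
    p <- parcellations[[nm]]
    if (!same_geometry(reference, p))
      stop_geometry_mismatch(paste0("parcellation '", nm, "'"))
    present <- sort(unique(p$labels[p$labels > 0L]))
    if (!all(present %in% label_tables[[nm]]$label))
      stop("label table for '", nm, "' does not cover all labels present",
           call. = FALSE)
  }
  structure(list(reference = reference, hemispheres = hemispheres,
                 parcellations = parcellations, label_tables = label_tables),
            class = "atlas_bundle")
}

#' Estimate a patient-to-reference transform
#'
#' The built-in \code{centered_affine} method fits an axis-aligned affine
#' by moment matching: per-axis scale from the ratio of
#' intensity-weighted second moments, translation from the
#' intensity-weighted centers of mass. It is a coarse global alignment
#' sufficient for region-overlap profiling of synthetic data; a
#' deformable registration backend can be slotted in as an external
#' transform for real scans.
#'
#' @param moving patient [volumetric_image].
#' @param reference reference [volumetric_image].
#' @param method \code{"centered_affine"}.
#' @return A [spatial_transform] mapping moving physical space to
#'   reference physical space.
#' @export
estimate_transform <- function(moving, reference,
                               method = c("centered_affine")) {
  method <- match.arg(method)
  mom <- function(img) {
    v <- img$voxels
    w <- v - min(v)
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0)
      stop("registration failure: degenerate (constant or empty) image",
           call. = FALSE)
    idx <- arrayInd(seq_along(w), dim(v))
    pts <- index_to_physical(img, idx)
    wv <- as.numeric(w)
    com <- colSums(pts * wv) / tot
    sd <- sqrt(colSums(sweep(pts, 2L, com)^2 * wv) / tot)
    if (any(sd <= 0))
      stop("registration failure: image has no spatial extent along an axis",
           call. = FALSE)
    list(com = com, sd = sd)
  }
  m <- mom(moving); r <- mom(reference)
  scale <- r$sd / m$sd
  A <- diag(scale)
  spatial_transform("affine", matrix = A,
                    translation = r$com - as.numeric(A %*% m$com))
}

#' Warp a label mask onto a reference grid
#'
#' Nearest-neighbor resampling of a mask through a spatial transform:
#' each reference voxel center is mapped back into moving space through
#' the inverse transform and sampled. The output label set is always a
#' subset of the input's.
#'
#' @param mask [label_mask] in moving space.
#' @param transform [spatial_transform] from moving to reference space.
#' @param reference_grid image or mask supplying the output geometry.
#' @export
warp_mask <- function(mask, transform, reference_grid) {
  sh <- image_shape(reference_grid)
  idx <- arrayInd(seq_len(prod(sh)), sh)
  pts_ref <- index_to_physical(reference_grid, idx)
  pts_mov <- apply_transform(transform, pts_ref, "inverse")
  ci <- physical_to_index(mask, pts_mov)
  ri <- round(ci)
  dm <- image_shape(mask)
  ok <- ri[, 1L] >= 1 & ri[, 1L] <= dm[1L] &
        ri[, 2L] >= 1 & ri[, 2L] <= dm[2L] &
        ri[, 3L] >= 1 & ri[, 3L] <= dm[3L]
  out <- integer(prod(sh))
  lin <- (ri[ok, 3L] - 1) * dm[1L] * dm[2L] + (ri[ok, 2L] - 1) * dm[1L] +
    ri[ok, 1L]
  out[ok] <- mask$labels[lin]
  grid <- volumetric_image(array(0, sh), spacing = geom_spacing(reference_grid),
                           origin = geom_origin(reference_grid),
                           orientation = geom_orientation(reference_grid))
  label_mask(array(out, sh), grid, kind = mask$kind)
}

#' Region-overlap location profile of a tumor
#'
#' For each structure of a parcellation, the percentage of the tumor's
#' volume falling inside that structure; tumor voxels with parcellation
#' label 0 are reported under \code{"unlabeled"}. Percentages sum to 100.
#'
#' @param tumor non-empty binary [label_mask] on the parcellation grid.
#' @param parcellation [label_mask] of kind \code{"parcellation"}.
#' @param label_table optional data.frame (\code{label}, \code{name});
#'   unnamed labels are reported as \code{label_<k>}.
#' @return Named numeric vector of percentages (includes every table
#'   entry, zero or not, plus \code{"unlabeled"}).
#' @export
region_overlap_profile <- function(tumor, parcellation, label_table = NULL) {
  if (!same_geometry(tumor, parcellation)) stop_geometry_mismatch("parcellation")
  n_tumor <- sum(tumor$labels > 0L)
  if (n_tumor == 0L) stop("empty tumor mask: no location profile", call. = FALSE)
  labs <- parcellation$labels[tumor$labels > 0L]
  region_name <- function(l) {
    if (!is.null(label_table)) {
      i <- match(l, label_table$label)
      if (!is.na(i)) return(as.character(label_table$name[i]))
    }
    paste0("label_", l)
  }
  all_labels <- if (!is.null(label_table)) sort(unique(label_table$label))
                else sort(unique(labs[labs > 0L]))
  counts <- vapply(all_labels, function(l) sum(labs == l), numeric(1))
  prof <- c(100 * counts / n_tumor, unlabeled = 100 * sum(labs == 0L) / n_tumor)
  names(prof) <- c(vapply(all_labels, region_name, ""), "unlabeled")
  prof
}

#' Write / read an atlas bundle directory
#'
#' On-disk layout: \code{reference.nii.gz}, \code{hemispheres.nii.gz},
#' and per parcellation \code{parcellation_<name>.nii.gz} plus
#' \code{labels_<name>.csv} with columns \code{label,name}.
#'
#' @param atlas an [atlas_bundle].
#' @param dir directory path.
#' @export
write_atlas_bundle <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(atlas$reference, file.path(dir, "reference.nii.gz"))
  write_volume(atlas$hemispheres, file.path(dir, "hemispheres.nii.gz"))
  for (nm in names(atlas$parcellations)) {
    write_volume(atlas$parcellations[[nm]],
                 file.path(dir, paste0("parcellation_", nm, ".nii.gz")))
    utils::write.csv(atlas$label_tables[[nm]],
                     file.path(dir, paste0("labels_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_atlas_bundle
#' @export
read_atlas_bundle <- function(dir) {
  reference <- read_volume(file.path(dir, "reference.nii.gz"))
  hem <- read_mask(file.path(dir, "hemispheres.nii.gz"), kind = "parcellation")
  files <- list.files(dir, pattern = "^parcellation_.*\\.nii\\.gz$")
  nms <- sub("^parcellation_(.*)\\.nii\\.gz$", "\\1", files)
  parc <- stats::setNames(lapply(files, function(f)
    read_mask(file.path(dir, f), kind = "parcellation")), nms)
  tabs <- stats::setNames(lapply(nms, function(nm)
    utils::read.csv(file.path(dir, paste0("labels_", nm, ".csv")))), nms)
  atlas_bundle(reference, hem, parc, tabs)
}

#' Serialize a transform to JSON
#' @param tf a [spatial_transform] (internal kind).
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  if (tf$kind == "external")
    stop("external transforms have no parameter serialization", call. = FALSE)
  jsonlite::write_json(list(kind = tf$kind, matrix = tf$matrix,
                            translation = tf$translation),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spatial_transform(x$kind, matrix = x$matrix, translation = x$translation)
}
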