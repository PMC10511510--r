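#' Preprocessing configuration
#'
#' Bundles the parameters of the preprocessing chain applied before tumor
#' inference: isotropic resampling (default 0.75 mm), optional
#' skull-stripping with a brain mask, clipping of the top fraction of
#' intensities (default 0.05% highest values), and affine normalization
#' of the intensity range (default to \code{[0, 1]}).
#'
#' @param target_spacing_mm isotropic resampling target, mm.
#' @param clip_upper_fraction fraction of highest intensities clipped to
#'   the corresponding quantile; in \code{[0, 1)}.
#' @param skull_strip apply the brain mask before normalization.
#' @param normalization_range length-2 \code{c(low, high)} output range.
#' @param clip_within_brain compute the clipping quantile over
#'   brain-masked voxels only, rather than the whole volume.
#' @export
preprocessing_config <- function(target_spacing_mm = 0.75,
                                 clip_upper_fraction = 0.0005,
                                 skull_strip = TRUE,
                                 normalization_range = c(0, 1),
                                 clip_within_brain = FALSE) {
  if (!is.numeric(target_spacing_mm) || target_spacing_mm <= 0)
    stop("'target_spacing_mm' must be > 0", call. = FALSE)
  if (clip_upper_fraction < 0 || clip_upper_fraction >= 1)
    stop("'clip_upper_fraction' must be in [0, 1)", call. = FALSE)
  if (length(normalization_range) != 2L ||
      normalization_range[2L] <= normalization_range[1L])
    stop("'normalization_range' must be c(low, high) with low < high",
         call. = FALSE)
  structure(list(target_spacing_mm = target_spacing_mm,
                 clip_upper_fraction = clip_upper_fraction,
                 skull_strip = isTRUE(skull_strip),
                 normalization_range = as.numeric(normalization_range),
                 clip_within_brain = isTRUE(clip_within_brain)),
            class = "preprocessing_config")
}

## Resample a voxel array from one grid onto a target shape/spacing pair
## sharing orientation. Cell-centered alignment: output cell j spans the
## same physical slab as input coordinate 0.5 + (j - 0.5) * out/in, so
## both grids tile the same extent symmetrically and no half-voxel bias
## accumulates at the volume edges.
resample_array <- function(voxels, in_spacing, out_shape, out_spacing,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(voxels)
  coord <- lapply(1:3, function(a) {
    ci <- 0.5 + (seq_len(out_shape[a]) - 0.5) * out_spacing[a] / in_spacing[a]
    pmin(pmax(ci, 1), dm[a])
  })
  if (interpolation == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(coord[[a]]), 1L), dm[a]))
    return(voxels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(floor(coord[[a]]), dm[a] - (dm[a] > 1L)))
  fr <- lapply(1:3, function(a) coord[[a]] - lo[[a]])
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, dm[a]))
  out <- array(0, out_shape)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wx <- if (cx) fr[[1L]] else 1 - fr[[1L]]
    wy <- if (cy) fr[[2L]] else 1 - fr[[2L]]
    wz <- if (cz) fr[[3L]] else 1 - fr[[3L]]
    w <- outer(outer(wx, wy), wz)
    ix <- if (cx) hi[[1L]] else lo[[1L]]
    iy <- if (cy) hi[[2L]] else lo[[2L]]
    iz <- if (cz) hi[[3L]] else lo[[3L]]
    out <- out + w * voxels[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample a volume to isotropic voxel spacing
#'
#' The output shape per axis is \code{round(shape * spacing / target)},
#' which preserves the physical extent to within one voxel. Linear
#' interpolation is used for images; nearest-neighbor must be used for
#' label data so that no new label values are invented.
#'
#' @param image a [volumetric_image] or [label_mask].
#' @param target_spacing_mm target isotropic spacing, mm (> 0).
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return Object of the same class as \code{image} on the resampled grid.
#' @examples
#' img <- volumetric_image(array(rnorm(64^3), c(64, 64, 64)),
#'                         spacing = c(1.5, 1.5, 1.5))
#' iso <- resample_to_isotropic(img, 0.75)
#' image_shape(iso)  # 128 x 128 x 128
#' @export
resample_to_isotropic <- function(image, target_spacing_mm = 0.75,
                                  interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is.numeric(target_spacing_mm) || length(target_spacing_mm) != 1L ||
      !is.finite(target_spacing_mm) || target_spacing_mm <= 0)
    stop("'target_spacing_mm' must be a positive scalar", call. = FALSE)
  is_mask <- inherits(image, "label_mask")
  if (is_mask && interpolation != "nearest")
    stop("label masks must be resampled with nearest-neighbor interpolation",
         call. = FALSE)
  in_spacing <- geom_spacing(image)
  out_spacing <- rep(target_spacing_mm, 3L)
  out_shape <- pmax(1L, as.integer(round(image_shape(image) * in_spacing /
                                           target_spacing_mm)))
  arr <- if (is_mask) image$labels else image$voxels
  res <- resample_array(arr, in_spacing, out_shape, out_spacing, interpolation)
  ## cell-centered resampling moves the first voxel center by half the
  ## spacing difference; shift the origin so physical positions agree
  origin <- geom_origin(image) +
    as.numeric(geom_orientation(image) %*% ((out_spacing - in_spacing) / 2))
  grid <- volumetric_image(array(0, out_shape), spacing = out_spacing,
                           origin = origin,
                           orientation = geom_orientation(image))
  if (is_mask) label_mask(res, grid, kind = image$kind)
  else { grid$voxels <- res; grid }
}

#' Clip extreme intensities and normalize the range
#'
#' Values above the \code{1 - clip_upper_fraction} quantile
#' (linear-interpolation quantile over the flattened volume, or over
#' \code{mask} voxels when given) are set to that quantile, removing
#' bright outliers, after which the volume is affinely mapped so its
#' minimum and maximum hit \code{range}. A constant volume maps to all
#' \code{range[1]}.
#'
#' @param image a [volumetric_image] with finite voxel values.
#' @param clip_upper_fraction fraction of the highest values to clip
#'   (default 0.0005, i.e. the 0.05% highest values).
#' @param range length-2 output range \code{c(low, high)}.
#' @param mask optional brain [label_mask]: quantile computed within it.
#' @return A [volumetric_image] on the same grid.
#' @export
clip_and_normalize <- function(image, clip_upper_fraction = 0.0005,
                               range = c(0, 1), mask = NULL) {
  if (clip_upper_fraction < 0 || clip_upper_fraction >= 1)
    stop("'clip_upper_fraction' must be in [0, 1)", call. = FALSE)
  v <- image$voxels
  if (any(!is.finite(v)))
    stop("voxel values must be finite (NaN/Inf found)", call. = FALSE)
  pool <- if (is.null(mask)) v else {
    if (!same_geometry(image, mask)) stop_geometry_mismatch("clipping mask")
    v[mask$labels > 0L]
  }
  if (length(pool) == 0L) pool <- v
  q <- stats::quantile(pool, probs = 1 - clip_upper_fraction, names = FALSE,
                       type = 7)
  v[v > q] <- q
  lo <- min(v); hi <- max(v)
  v <- if (hi > lo) range[1L] + (v - lo) / (hi - lo) * (range[2L] - range[1L])
       else array(range[1L], dim(v))
  out <- image
  out$voxels <- v
  out
}

#' Zero out non-brain voxels (skull stripping)
#'
#' Voxels outside the brain mask are set to the background value 0 (the
#' low end of the normalized intensity range); voxels inside are
#' unchanged. The mask must share the image grid.
#'
#' @param image a [volumetric_image].
#' @param brain a [label_mask] of kind \code{"brain"} on the same grid.
#' @export
apply_brain_mask <- function(image, brain) {
  if (!inherits(brain, "label_mask") || brain$kind != "brain")
    stop("'brain' must be a label_mask of kind 'brain'", call. = FALSE)
  if (!same_geometry(image, brain)) stop_geometry_mismatch("brain mask")
  out <- image
  out$voxels <- image$voxels * (brain$labels > 0L)
  out
}

#' Foreground volume of a mask in milliliters
#'
#' Foreground voxel count times the voxel volume in mm^3, divided by 1000.
#'
#' @param mask a binary [label_mask] (kind \code{"tumor"} or \code{"brain"}).
#' @return Volume in ml (non-negative; 0 for an empty mask).
#' @export
mask_volume_ml <- function(mask) {
  if (!inherits(mask, "label_mask") || !mask$kind %in% c("tumor", "brain"))
    stop("'mask' must be a binary tumor or brain label_mask", call. = FALSE)
  sum(mask$labels > 0L) * voxel_volume_mm3(mask) / 1000
}

#' Run the full preprocessing chain
#'
#' Isotropic resampling, optional skull-stripping, intensity clipping and
#' normalization, in that order — the chain applied ahead of patch-wise
#' tumor inference.
#'
#' @param image input [volumetric_image].
#' @param config a [preprocessing_config].
#' @param brain optional brain mask on the input grid (resampled along
#'   with the image); required when \code{config$skull_strip} is TRUE.
#' @return A list with the preprocessed \code{image} and the resampled
#'   \code{brain} mask (or NULL).
#' @export
preprocess_image <- function(image, config = preprocessing_config(),
                             brain = NULL) {
  iso <- resample_to_isotropic(image, config$target_spacing_mm, "linear")
  brain_iso <- NULL
  if (!is.null(brain)) {
    if (!same_geometry(image, brain)) stop_geometry_mismatch("brain mask")
    brain_iso <- resample_to_isotropic(brain, config$target_spacing_mm,
                                       "nearest")
  }
  pool_mask <- if (config$clip_within_brain) brain_iso else NULL
  iso <- clip_and_normalize(iso, config$clip_upper_fraction,
                            config$normalization_range, mask = pool_mask)
  if (config$skull_strip) {
    if (is.null(brain_iso))
      stop("skull_strip requested but no brain mask supplied", call. = FALSE)
    iso <- apply_brain_mask(iso, brain_iso)
  }
  list(image = iso, brain = brain_iso)
}
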