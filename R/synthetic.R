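## Deterministic synthetic data: head phantoms, ellipsoid tumors, toy
## atlases, voxel-local predictors, and multi-timestamp cohort trees.
## These stand in for patient data, which are GDPR-restricted and cannot
## be shipped; every generator is seed-deterministic and every ground
## truth is derived from the generating parameters, not read back from
## the produced voxels.

#' Head phantom specification
#'
#' @param shape length-3 integer grid shape.
#' @param spacing_mm length-3 voxel spacing, mm.
#' @param seed integer RNG seed (the phantom is bit-identical per spec).
#' @param brain_radius_fraction brain ellipsoid radii as a fraction of
#'   the head ellipsoid radii.
#' @param noise_sd additive Gaussian noise sd (image intensity units).
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing_mm = c(1, 1, 1),
                         seed = 42L, brain_radius_fraction = 0.8,
                         noise_sd = 0.02) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("phantom shape must be 3 integers >= 8", call. = FALSE)
  if (brain_radius_fraction <= 0 || brain_radius_fraction >= 1)
    stop("'brain_radius_fraction' must be in (0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  list(shape = shape, spacing_mm = as.numeric(spacing_mm),
       seed = as.integer(seed),
       brain_radius_fraction = brain_radius_fraction, noise_sd = noise_sd)
}

## logical ellipsoid rasterization at voxel centers, via separable sums
ellipsoid_array <- function(geom, center_mm, radii_mm) {
  sh <- image_shape(geom); sp <- geom_spacing(geom); o <- geom_origin(geom)
  d2 <- lapply(1:3, function(a) {
    x <- o[a] + (seq_len(sh[a]) - 1) * sp[a]
    ((x - center_mm[a]) / radii_mm[a])^2
  })
  outer(outer(d2[[1L]], d2[[2L]], `+`), d2[[3L]], `+`) <= 1
}

#' Generate a head phantom with an exact brain mask
#'
#' An ellipsoidal bright "brain" (intensity 0.7) nested inside a darker
#' "head" (0.3) on a zero background, with optional additive Gaussian
#' noise. The brain mask is the exact rasterization of the brain
#' ellipsoid, so downstream volume checks can compare against the
#' analytic ellipsoid volume.
#'
#' @param spec a [phantom_spec()].
#' @return List: \code{image} ([volumetric_image]), \code{brain}
#'   ([label_mask]), \code{brain_center_mm}, \code{brain_radii_mm},
#'   \code{brain_volume_ml} (analytic 4/3 pi abc).
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  sh <- spec$shape; sp <- spec$spacing_mm
  extent <- (sh - 1) * sp
  center <- extent / 2
  head_radii <- 0.47 * sh * sp
  brain_radii <- spec$brain_radius_fraction * head_radii
  grid <- volumetric_image(array(0, sh), spacing = sp)
  head <- ellipsoid_array(grid, center, head_radii)
  brain <- ellipsoid_array(grid, center, brain_radii)
  vox <- array(0, sh)
  vox[head] <- 0.3
  vox[brain] <- 0.7
  if (spec$noise_sd > 0) {
    rng <- local({ set.seed(spec$seed); stats::rnorm(prod(sh), 0, spec$noise_sd) })
    vox <- vox + array(rng, sh)
  }
  img <- grid
  img$voxels <- vox
  list(image = img,
       brain = label_mask(array(as.integer(brain), sh), grid, kind = "brain"),
       brain_center_mm = center, brain_radii_mm = brain_radii,
       brain_volume_ml = 4 / 3 * pi * prod(brain_radii) / 1000)
}

#' Tumor specification: a list of ellipsoidal foci
#'
#' @param foci list of foci, each a list with \code{center_mm} (length
#'   3), \code{radii_mm} (length 3 or scalar), and optional
#'   \code{intensity_offset} (default 0.35).
#' @param seed integer seed (reserved for stochastic extensions).
#' @export
tumor_spec <- function(foci, seed = 1L) {
  foci <- lapply(foci, function(f) {
    if (is.null(f$center_mm) || is.null(f$radii_mm))
      stop("each focus needs 'center_mm' and 'radii_mm'", call. = FALSE)
    f$radii_mm <- rep(as.numeric(f$radii_mm), length.out = 3L)
    if (any(f$radii_mm <= 0)) stop("focus radii must be > 0", call. = FALSE)
    if (is.null(f$intensity_offset)) f$intensity_offset <- 0.35
    f
  })
  list(foci = foci, seed = as.integer(seed))
}

#' Paint ellipsoid tumor foci into a head phantom
#'
#' Rasterizes the union of the focus ellipsoids as the ground-truth
#' tumor mask and raises the image intensity inside each focus. Every
#' focus must lie inside the brain ellipsoid (checked conservatively on
#' the bounding extents). Analytic per-focus volumes 4/3 pi abc are
#' returned as ground truth.
#'
#' @param spec a [tumor_spec()].
#' @param phantom output of [make_head_phantom()].
#' @return List: \code{image} (tumor-enhanced), \code{mask} (binary
#'   tumor [label_mask]), \code{foci} data.frame with
#'   \code{analytic_volume_ml} per focus.
#' @export
make_tumor <- function(spec, phantom) {
  grid <- phantom$image
  bc <- phantom$brain_center_mm; br <- phantom$brain_radii_mm
  for (f in spec$foci) {
    ## sufficient containment condition for axis-aligned ellipsoids:
    ## offset (in brain-normalized units) plus worst-case focus reach
    reach <- sqrt(sum(((f$center_mm - bc) / br)^2)) + max(f$radii_mm / br)
    if (reach > 1)
      stop("tumor focus extends outside the brain ellipsoid", call. = FALSE)
  }
  sh <- image_shape(grid)
  mask <- array(FALSE, sh)
  vox <- grid$voxels
  for (f in spec$foci) {
    e <- ellipsoid_array(grid, f$center_mm, f$radii_mm)
    vox[e] <- vox[e] + f$intensity_offset
    mask <- mask | e
  }
  img <- grid
  img$voxels <- vox
  foci_df <- do.call(rbind, lapply(seq_along(spec$foci), function(i) {
    f <- spec$foci[[i]]
    data.frame(focus = i,
               center_x_mm = f$center_mm[1L], center_y_mm = f$center_mm[2L],
               center_z_mm = f$center_mm[3L],
               analytic_volume_ml = 4 / 3 * pi * prod(f$radii_mm) / 1000)
  }))
  list(image = img,
       mask = label_mask(array(as.integer(mask), sh), grid, kind = "tumor"),
       foci = foci_df)
}

#' Build a toy atlas bundle on a phantom grid
#'
#' Hemispheres split the brain on the central voxel plane of the first
#' (left-right) axis; a "cortical" parcellation divides the brain into
#' \code{n_regions} contiguous slabs along the third axis; a
#' "subcortical" parcellation marks a central core (half-radius
#' ellipsoid). Hemisphere masks are disjoint and cover the brain mask
#' exactly. This is a synthetic stand-in for a standard template bundle,
#' which is not redistributed.
#'
#' @param phantom output of [make_head_phantom()] defining the reference
#'   grid, template image and brain.
#' @param n_regions number of cortical slabs (>= 1).
#' @return An [atlas_bundle].
#' @export
make_toy_atlas <- function(phantom, n_regions = 4L) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("'n_regions' must be >= 1", call. = FALSE)
  brain <- phantom$brain$labels > 0L
  sh <- dim(brain)
  idx1 <- slice.index(brain, 1L)
  hem <- array(0L, sh)
  mid <- floor(sh[1L] / 2)
  hem[brain & idx1 <= mid] <- 1L
  hem[brain & idx1 > mid] <- 2L
  idx3 <- slice.index(brain, 3L)
  zr <- range(idx3[brain])
  edges <- round(seq(zr[1L], zr[2L] + 1L, length.out = n_regions + 1L))
  cort <- array(0L, sh)
  for (k in seq_len(n_regions))
    cort[brain & idx3 >= edges[k] & idx3 < edges[k + 1L]] <- k
  cort[brain & idx3 == zr[2L] & cort == 0L] <- n_regions
  core <- ellipsoid_array(phantom$image, phantom$brain_center_mm,
                          phantom$brain_radii_mm / 2)
  sub <- array(0L, sh)
  sub[core & brain] <- 1L
  grid <- phantom$image
  atlas_bundle(
    reference = phantom$image,
    hemispheres = label_mask(hem, grid, kind = "parcellation"),
    parcellations = list(
      cortical = label_mask(cort, grid, kind = "parcellation"),
      subcortical = label_mask(sub, grid, kind = "parcellation")),
    label_tables = list(
      cortical = data.frame(label = seq_len(n_regions),
                            name = paste0("region_", seq_len(n_regions))),
      subcortical = data.frame(label = 1L, name = "central_core")))
}

#' Voxel-local threshold predictor
#'
#' Emits probability 1 where the normalized intensity exceeds the
#' threshold, else 0. Being purely voxel-local, its patch-wise result
#' must equal single-pass whole-volume application — the reference
#' predictor for exercising the stitching machinery; with a distinct
#' tumor intensity it recovers synthetic tumor masks exactly.
#'
#' @param threshold scalar in \code{[0, 1]}.
#' @param input_patch_shape optional fixed patch shape.
#' @return A [predictor].
#' @export
make_threshold_predictor <- function(threshold = 0.5,
                                     input_patch_shape = NULL) {
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must be in [0, 1]", call. = FALSE)
  force(threshold)
  predictor(function(patch) array(as.numeric(patch > threshold), dim(patch)),
            input_patch_shape = input_patch_shape,
            name = sprintf("threshold_%g", threshold))
}

#' Generate a multi-timestamp synthetic cohort on disk
#'
#' Writes \code{n_patients} patient folders, each with a preoperative
#' (\code{T0}) and postoperative (\code{T1}) timestamp subfolder holding
#' a phantom image, the ground-truth tumor mask and the brain mask as
#' NIfTI. Preoperative tumors are one or two left-hemisphere ellipsoid
#' foci; postoperative volumes keep a concentric residual (or none, for
#' the first patient, giving a complete resection). A JSON manifest
#' records, per patient, the analytic focus volumes and the voxel-grid
#' volumes recomputed from the generating geometry, plus the resulting
#' extent of resection.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer master seed; everything is reproducible from it.
#' @param out_dir output directory (created).
#' @param shape,spacing_mm phantom grid.
#' @return The manifest list, invisibly; also written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
make_synthetic_cohort <- function(n_patients, seed = 42L, out_dir,
                                  shape = c(64L, 64L, 64L),
                                  spacing_mm = c(1, 1, 1)) {
  if (n_patients < 1L) stop("'n_patients' must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create cohort directory: ", out_dir, call. = FALSE)
  manifest <- list(seed = as.integer(seed), patients = list())
  for (i in seq_len(n_patients)) {
    set.seed(seed * 1000L + i)
    pid <- sprintf("patient_%03d", i)
    ph <- make_head_phantom(phantom_spec(shape = shape,
                                         spacing_mm = spacing_mm,
                                         seed = seed * 1000L + i,
                                         noise_sd = 0.02))
    bc <- ph$brain_center_mm; br <- ph$brain_radii_mm
    ## tumor radii span roughly one-tenth of the brain's linear scale up
    ## to a large lesion, so cohort volumes straddle the 2 ml cut-off
    r_main <- stats::runif(1, 0.20, 0.40) * min(br)
    c_main <- bc + c(-0.25 * br[1L],
                     stats::runif(1, -0.10, 0.10) * br[2L],
                     stats::runif(1, -0.10, 0.10) * br[3L])
    foci <- list(list(center_mm = c_main, radii_mm = r_main))
    if (i %% 2L == 0L) {          # every second patient is bifocal
      r_sat <- 0.14 * min(br)
      c_sat <- bc + c(-0.25 * br[1L], 0.5 * br[2L], -0.35 * br[3L])
      foci <- c(foci, list(list(center_mm = c_sat, radii_mm = r_sat)))
    }
    pre <- make_tumor(tumor_spec(foci), ph)
    residual_scale <- if (i == 1L) 0 else stats::runif(1, 0.3, 0.6)
    post_foci <- if (residual_scale > 0)
      list(list(center_mm = c_main, radii_mm = r_main * residual_scale))
    else list()
    post <- if (length(post_foci)) make_tumor(tumor_spec(post_foci), ph)
            else list(image = ph$image,
                      mask = label_mask(array(0L, shape), ph$image,
                                        kind = "tumor"),
                      foci = NULL)
    pdir <- file.path(out_dir, pid)
    write_volume(pre$image, file.path(pdir, "T0", "image.nii.gz"))
    write_volume(pre$mask, file.path(pdir, "T0", "label_tumor.nii.gz"))
    write_volume(ph$brain, file.path(pdir, "T0", "label_brain.nii.gz"))
    write_volume(post$image, file.path(pdir, "T1", "image.nii.gz"))
    write_volume(post$mask, file.path(pdir, "T1", "label_tumor.nii.gz"))
    write_volume(ph$brain, file.path(pdir, "T1", "label_brain.nii.gz"))
    ## voxel-grid volumes recomputed from the generating ellipsoid
    ## parameters (independent of the files just written)
    vvol <- prod(spacing_mm) / 1000
    count_union <- function(fl) {
      if (!length(fl)) return(0L)
      m <- Reduce(`|`, lapply(fl, function(f)
        ellipsoid_array(ph$image, f$center_mm,
                        rep(f$radii_mm, length.out = 3L))))
      sum(m)
    }
    pre_vox_ml <- count_union(foci) * vvol
    post_vox_ml <- count_union(post_foci) * vvol
    manifest$patients[[pid]] <- list(
      patient_id = pid,
      n_preop_foci = length(foci),
      preop_analytic_ml = sum(vapply(foci, function(f)
        4 / 3 * pi * prod(rep(f$radii_mm, length.out = 3L)) / 1000,
        numeric(1))),
      preop_voxel_ml = pre_vox_ml,
      postop_analytic_ml = sum(vapply(post_foci, function(f)
        4 / 3 * pi * prod(rep(f$radii_mm, length.out = 3L)) / 1000,
        numeric(1))),
      postop_voxel_ml = post_vox_ml,
      eor_pct = 100 * (pre_vox_ml - post_vox_ml) / pre_vox_ml,
      brain_analytic_ml = ph$brain_volume_ml)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
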