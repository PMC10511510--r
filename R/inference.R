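#' Pluggable voxel-classifier contract
#'
#' A predictor wraps any function mapping a 3D scalar patch to a
#' same-shape per-voxel probability map in \code{[0, 1]}. Trained
#' segmentation networks (e.g. exported to an interchange runtime) can be
#' plugged in through this contract; [make_threshold_predictor()] provides
#' a synthetic, voxel-local stand-in for testing the machinery.
#'
#' @param fun function taking a 3D array and returning a 3D array of the
#'   same shape with values in \code{[0, 1]}.
#' @param input_patch_shape optional fixed input shape (length-3 integer);
#'   \code{NULL} means the predictor accepts any patch shape.
#' @param name short label used in provenance records.
#' @export
predictor <- function(fun, input_patch_shape = NULL, name = "predictor") {
  if (!is.function(fun)) stop("'fun' must be a function", call. = FALSE)
  if (!is.null(input_patch_shape)) {
    input_patch_shape <- as.integer(input_patch_shape)
    if (length(input_patch_shape) != 3L || any(input_patch_shape < 1L))
      stop("'input_patch_shape' must be 3 positive integers", call. = FALSE)
  }
  structure(list(fun = fun, input_patch_shape = input_patch_shape,
                 name = name),
            class = "predictor")
}

#' @rdname predictor
#' @param pred a \code{predictor}.
#' @param patch 3D array to classify.
#' @export
apply_predictor <- function(pred, patch) {
  if (!inherits(pred, "predictor")) stop("not a predictor", call. = FALSE)
  if (!is.null(pred$input_patch_shape) &&
      !identical(dim(patch), pred$input_patch_shape))
    stop("predictor contract violation: patch shape ",
         paste(dim(patch), collapse = "x"), " != declared input shape ",
         paste(pred$input_patch_shape, collapse = "x"), call. = FALSE)
  out <- pred$fun(patch)
  if (!is.array(out) || !identical(dim(out), dim(patch)))
    stop("predictor contract violation: output shape differs from input",
         call. = FALSE)
  if (any(!is.finite(out)) || min(out) < 0 || max(out) > 1)
    stop("predictor contract violation: outputs must be in [0, 1]",
         call. = FALSE)
  out
}

#' Plan a sliding-window patch grid over a volume
#'
#' Tiles a volume with fixed-size 3D patches (default 160^3 voxels, the
#' patch dimension used for tumor inference). Per axis, patch starts
#' advance by \code{patch * (1 - min_overlap_fraction)} voxels, using the
#' minimum number of patches that covers the axis; the final patch is
#' shifted back so it ends exactly at the volume edge. Volumes smaller
#' than the patch are zero-padded at the high end of each axis.
#'
#' @param volume_shape length-3 integer volume shape.
#' @param patch_shape length-3 integer patch shape (default \code{c(160,
#'   160, 160)}).
#' @param min_overlap_fraction minimum fractional overlap between
#'   successive patches, in \code{[0, 1)}; 0 means abutting tiles.
#' @return A \code{patch_grid}: \code{patch_shape}, \code{starts}
#'   (matrix of 1-based corner indices into the padded volume),
#'   \code{padding} (per-axis high-end pad), \code{padded_shape}.
#' @examples
#' g <- plan_patch_grid(c(200, 200, 200), c(160, 160, 160))
#' nrow(g$starts)  # 8 patches
#' @export
plan_patch_grid <- function(volume_shape, patch_shape = c(160L, 160L, 160L),
                            min_overlap_fraction = 0) {
  volume_shape <- as.integer(volume_shape)
  patch_shape <- as.integer(patch_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L))
    stop("'volume_shape' must be 3 positive integers", call. = FALSE)
  if (length(patch_shape) != 3L || any(patch_shape < 1L))
    stop("'patch_shape' must be 3 positive integers", call. = FALSE)
  if (min_overlap_fraction < 0 || min_overlap_fraction >= 1)
    stop("'min_overlap_fraction' must be in [0, 1)", call. = FALSE)
  padding <- pmax(0L, patch_shape - volume_shape)
  padded <- volume_shape + padding
  axis_starts <- lapply(1:3, function(a) {
    n <- padded[a]; p <- patch_shape[a]
    if (n <= p) return(1L)
    step <- max(1L, as.integer(floor(p * (1 - min_overlap_fraction))))
    k <- as.integer(ceiling((n - p) / step)) + 1L
    s <- 1L + (seq_len(k) - 1L) * step
    s[k] <- n - p + 1L                     # edge-shifted final patch
    unique(s)
  })
  starts <- as.matrix(expand.grid(axis_starts[[1L]], axis_starts[[2L]],
                                  axis_starts[[3L]], KEEP.OUT.ATTRS = FALSE))
  dimnames(starts) <- NULL
  structure(list(patch_shape = patch_shape, starts = starts,
                 padding = padding, padded_shape = padded,
                 volume_shape = volume_shape,
                 min_overlap_fraction = min_overlap_fraction),
            class = "patch_grid")
}

#' Patch-wise (sliding window) inference
#'
#' Runs the predictor over every patch of the grid and fuses overlapping
#' predictions — the iterative inference mode used for tumor
#' segmentation, where the volume is larger than the network's receptive
#' field. Padding is constant 0 (the post-normalization background) and
#' is cropped from the output.
#'
#' @param image preprocessed [volumetric_image].
#' @param pred a [predictor]; if it declares a fixed input shape it must
#'   equal the grid's patch shape.
#' @param grid a patch grid from [plan_patch_grid()]; defaults to a grid
#'   planned over the image with the predictor's patch shape.
#' @param fusion \code{"mean"} (average overlapping probabilities) or
#'   \code{"max"}.
#' @return A [volumetric_image] probability map on the input grid, values
#'   in \code{[0, 1]}.
#' @export
predict_patchwise <- function(image, pred, grid = NULL,
                              fusion = c("mean", "max")) {
  fusion <- match.arg(fusion)
  if (is.null(grid)) {
    ps <- if (!is.null(pred$input_patch_shape)) pred$input_patch_shape
          else c(160L, 160L, 160L)
    grid <- plan_patch_grid(image_shape(image), ps)
  }
  if (!is.null(pred$input_patch_shape) &&
      !identical(pred$input_patch_shape, grid$patch_shape))
    stop("predictor input shape does not match grid patch shape",
         call. = FALSE)
  padded <- array(0, grid$padded_shape)
  sh <- image_shape(image)
  padded[seq_len(sh[1L]), seq_len(sh[2L]), seq_len(sh[3L])] <- image$voxels
  acc <- array(if (fusion == "mean") 0 else -Inf, grid$padded_shape)
  cnt <- if (fusion == "mean") array(0L, grid$padded_shape) else NULL
  p <- grid$patch_shape
  for (r in seq_len(nrow(grid$starts))) {
    s <- grid$starts[r, ]
    ix <- s[1L]:(s[1L] + p[1L] - 1L)
    iy <- s[2L]:(s[2L] + p[2L] - 1L)
    iz <- s[3L]:(s[3L] + p[3L] - 1L)
    prob <- apply_predictor(pred, padded[ix, iy, iz, drop = FALSE])
    if (fusion == "mean") {
      acc[ix, iy, iz] <- acc[ix, iy, iz] + prob
      cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
    } else {
      acc[ix, iy, iz] <- pmax(acc[ix, iy, iz], prob)
    }
  }
  fused <- if (fusion == "mean") acc / pmax(cnt, 1L) else acc
  fused <- fused[seq_len(sh[1L]), seq_len(sh[2L]), seq_len(sh[3L]),
                 drop = FALSE]
  out <- image
  out$voxels <- fused
  out
}

#' Single-shot inference over a downsampled volume
#'
#' The fast inference mode used for brain segmentation: the volume is
#' resampled to a small working shape, classified in one predictor call,
#' and the probability map is linearly upsampled back to the native grid
#' before binarization. Output geometry equals input geometry.
#'
#' @param image input [volumetric_image].
#' @param pred a [predictor] accepting the working shape.
#' @param working_shape length-3 integer downsampled shape.
#' @param threshold binarization threshold in \code{[0, 1]}.
#' @param kind kind of the output mask (default \code{"brain"}).
#' @return A binary [label_mask] on the native grid.
#' @export
predict_downsampled <- function(image, pred, working_shape = c(64L, 64L, 64L),
                                threshold = 0.5, kind = "brain") {
  working_shape <- as.integer(working_shape)
  if (length(working_shape) != 3L || any(working_shape < 1L))
    stop("'working_shape' must be 3 positive integers", call. = FALSE)
  sh <- image_shape(image)
  sp <- geom_spacing(image)
  work_spacing <- sh * sp / working_shape
  small <- resample_array(image$voxels, sp, working_shape, work_spacing,
                          "linear")
  prob_small <- apply_predictor(pred, small)
  prob <- resample_array(prob_small, work_spacing, sh, sp, "linear")
  pm <- image
  pm$voxels <- pmin(pmax(prob, 0), 1)
  binarize_probability(pm, threshold = threshold, kind = kind)
}

#' Threshold a probability map into a binary mask
#'
#' @param prob probability-map [volumetric_image] with values in
#'   \code{[0, 1]}.
#' @param threshold scalar in \code{[0, 1]}; voxels with probability
#'   \code{>= threshold} become foreground.
#' @param kind output mask kind, \code{"tumor"} or \code{"brain"}.
#' @export
binarize_probability <- function(prob, threshold = 0.5, kind = "tumor") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must be a scalar in [0, 1]", call. = FALSE)
  if (min(prob$voxels) < 0 || max(prob$voxels) > 1)
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  label_mask(array(as.integer(prob$voxels >= threshold), image_shape(prob)),
             prob, kind = kind)
}
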