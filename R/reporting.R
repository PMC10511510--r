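#' Reporting configuration
#'
#' Tunable thresholds for standardized report assembly. Defaults:
#' satellite foci below 0.1 ml are not reported individually (but still
#' count towards total volume); foci use full 26-connectivity; a tumor is
#' flagged as crossing the midline when at least 5% of its volume lies in
#' the minority hemisphere; resection classes follow configurable
#' residual-volume bands (complete = 0 ml residual, near-total <= 1 ml,
#' subtotal <= 5 ml, partial beyond).
#'
#' @param min_focus_ml minimum focus volume reported, ml.
#' @param connectivity focus connectivity: 6, 18 or 26.
#' @param crossing_threshold_pct midline-crossing threshold, % of tumor
#'   volume on the minority side.
#' @param resection_thresholds see [resection_thresholds()].
#' @export
report_config <- function(min_focus_ml = 0.1, connectivity = 26L,
                          crossing_threshold_pct = 5,
                          resection_thresholds = NULL) {
  if (is.null(resection_thresholds)) {
    resection_thresholds <- list(near_total_ml = 1, subtotal_ml = 5)
  }
  if (min_focus_ml < 0) stop("'min_focus_ml' must be >= 0", call. = FALSE)
  if (crossing_threshold_pct < 0 || crossing_threshold_pct > 50)
    stop("'crossing_threshold_pct' must be in [0, 50]", call. = FALSE)
  neighbor_offsets(connectivity)  # validates
  structure(list(min_focus_ml = min_focus_ml,
                 connectivity = as.integer(connectivity),
                 crossing_threshold_pct = crossing_threshold_pct,
                 resection_thresholds = resection_thresholds),
            class = "report_config")
}

#' Residual-volume bands for resection classification
#'
#' @param near_total_ml upper residual bound of the near-total class, ml.
#' @param subtotal_ml upper residual bound of the subtotal class, ml;
#'   must exceed \code{near_total_ml}.
#' @export
resection_thresholds <- function(near_total_ml = 1, subtotal_ml = 5) {
  if (!(0 < near_total_ml && near_total_ml < subtotal_ml))
    stop("non-monotone resection thresholds: need 0 < near_total < subtotal",
         call. = FALSE)
  list(near_total_ml = near_total_ml, subtotal_ml = subtotal_ml)
}

#' Tumor laterality in reference space
#'
#' Splits the tumor volume between the left and right hemisphere labels
#' of the atlas and derives the dominant side and a midline-crossing
#' flag. Percentages are relative to the tumor volume covered by the
#' hemisphere mask, so they always sum to 100.
#'
#' @param tumor_ref non-empty binary [label_mask] on the reference grid.
#' @param hemispheres hemisphere [label_mask] (1 = left, 2 = right).
#' @param crossing_threshold_pct the tumor crosses the midline when both
#'   sides hold more than this percentage of its volume.
#' @return List: \code{left_pct}, \code{right_pct},
#'   \code{midline_crossing}, \code{dominant} (ties go left).
#' @export
laterality_assessment <- function(tumor_ref, hemispheres,
                                  crossing_threshold_pct = 5) {
  if (!same_geometry(tumor_ref, hemispheres))
    stop_geometry_mismatch("hemisphere mask")
  if (sum(tumor_ref$labels > 0L) == 0L)
    stop("empty tumor mask: no laterality", call. = FALSE)
  hl <- hemispheres$labels[tumor_ref$labels > 0L]
  n_left <- sum(hl == 1L); n_right <- sum(hl == 2L)
  if (n_left + n_right == 0L)
    stop("tumor lies entirely outside the hemisphere mask", call. = FALSE)
  left_pct <- 100 * n_left / (n_left + n_right)
  right_pct <- 100 - left_pct
  list(left_pct = left_pct, right_pct = right_pct,
       midline_crossing = left_pct > crossing_threshold_pct &&
         right_pct > crossing_threshold_pct,
       dominant = if (left_pct >= right_pct) "left" else "right")
}

#' Extract tumor foci (connected components)
#'
#' Labels connected components of a binary tumor mask and returns those
#' at or above the minimum focus volume, ordered by descending volume.
#' Sub-threshold specks are dropped from the focus list but still count
#' towards the total tumor volume reported elsewhere.
#'
#' @param tumor binary [label_mask].
#' @param connectivity 6, 18 or 26.
#' @param min_focus_ml minimum reported focus volume, ml.
#' @return data.frame with \code{focus_id}, \code{volume_ml},
#'   \code{centroid_x_mm}, \code{centroid_y_mm}, \code{centroid_z_mm}.
#' @export
extract_foci <- function(tumor, connectivity = 26L, min_focus_ml = 0.1) {
  if (!inherits(tumor, "label_mask") || tumor$kind != "tumor")
    stop("'tumor' must be a label_mask of kind 'tumor'", call. = FALSE)
  comp <- label_components(tumor$labels, connectivity)
  n <- max(comp)
  empty <- data.frame(focus_id = integer(), volume_ml = numeric(),
                      centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                      centroid_z_mm = numeric())
  if (n == 0L) return(empty)
  vvol <- voxel_volume_mm3(tumor) / 1000
  rows <- lapply(seq_len(n), function(k) {
    lin <- which(comp == k)
    cen <- colMeans(index_to_physical(tumor, arrayInd(lin, dim(comp))))
    data.frame(focus_id = k, volume_ml = length(lin) * vvol,
               centroid_x_mm = cen[1L], centroid_y_mm = cen[2L],
               centroid_z_mm = cen[3L])
  })
  foci <- do.call(rbind, rows)
  foci <- foci[foci$volume_ml >= min_focus_ml, , drop = FALSE]
  if (nrow(foci) == 0L) return(empty)
  foci <- foci[order(-foci$volume_ml), , drop = FALSE]
  foci$focus_id <- seq_len(nrow(foci))
  rownames(foci) <- NULL
  foci
}

#' Extent of resection
#'
#' \code{EOR = 100 * (preop - postop) / preop}. A negative value means
#' the lesion grew between timestamps and is flagged in the postoperative
#' report.
#'
#' @param preop_ml preoperative tumor volume, ml (> 0).
#' @param postop_ml postoperative residual volume, ml (>= 0).
#' @return EOR in percent (at most 100; may be negative).
#' @export
extent_of_resection <- function(preop_ml, postop_ml) {
  if (!is.numeric(preop_ml) || preop_ml <= 0)
    stop("'preop_ml' must be > 0", call. = FALSE)
  if (!is.numeric(postop_ml) || postop_ml < 0)
    stop("'postop_ml' must be >= 0", call. = FALSE)
  100 * (preop_ml - postop_ml) / preop_ml
}

#' Classify the extent of resection
#'
#' Deterministic class from the residual volume: \code{"complete"} when
#' no residual remains, \code{"near-total"} up to
#' \code{near_total_ml}, \code{"subtotal"} up to \code{subtotal_ml},
#' \code{"partial"} beyond. The bands are fully configuration-driven so
#' they can track evolving clinical guidelines.
#'
#' @param residual_ml postoperative residual volume, ml.
#' @param eor_pct optional EOR, recorded but not used by the default
#'   banding.
#' @param thresholds a [resection_thresholds()] list.
#' @export
classify_resection_extent <- function(residual_ml, eor_pct = NULL,
                                      thresholds = resection_thresholds()) {
  if (!is.numeric(residual_ml) || residual_ml < 0)
    stop("'residual_ml' must be >= 0", call. = FALSE)
  if (!(0 < thresholds$near_total_ml &&
        thresholds$near_total_ml < thresholds$subtotal_ml))
    stop("inconsistent (non-monotone) resection thresholds", call. = FALSE)
  if (residual_ml == 0) "complete"
  else if (residual_ml <= thresholds$near_total_ml) "near-total"
  else if (residual_ml <= thresholds$subtotal_ml) "subtotal"
  else "partial"
}

#' Assemble the preoperative standardized report
#'
#' Gathers the preoperative tumor characteristics — volume (in both
#' patient and reference space, since registration changes volume),
#' laterality, multifocality with per-focus records, and one
#' region-overlap location profile per atlas parcellation — into a
#' single hierarchical record.
#'
#' @param tumor_patient_space non-empty binary [label_mask] on the native
#'   patient grid.
#' @param tumor_ref_space the same tumor warped onto the atlas reference
#'   grid.
#' @param atlas an [atlas_bundle].
#' @param config a [report_config()].
#' @param provenance named list of input identifiers (file names,
#'   timestamp labels, configuration hash) stored verbatim.
#' @return A \code{standardized_report} (phase \code{"preoperative"}).
#' @export
assemble_preop_report <- function(tumor_patient_space, tumor_ref_space, atlas,
                                  config = report_config(),
                                  provenance = list()) {
  if (sum(tumor_patient_space$labels > 0L) == 0L)
    stop("empty tumor mask: no preoperative report", call. = FALSE)
  if (sum(tumor_ref_space$labels > 0L) == 0L)
    stop("empty reference-space tumor mask", call. = FALSE)
  lat <- laterality_assessment(tumor_ref_space, atlas$hemispheres,
                               config$crossing_threshold_pct)
  foci <- extract_foci(tumor_patient_space, config$connectivity,
                       config$min_focus_ml)
  profiles <- lapply(names(atlas$parcellations), function(nm)
    as.list(region_overlap_profile(tumor_ref_space, atlas$parcellations[[nm]],
                                   atlas$label_tables[[nm]])))
  names(profiles) <- names(atlas$parcellations)
  report <- list(
    phase = "preoperative",
    volumes = list(patient_space_ml = mask_volume_ml(tumor_patient_space),
                   reference_space_ml = mask_volume_ml(tumor_ref_space)),
    laterality = lat,
    foci = foci,
    multifocal = nrow(foci) >= 2L,
    main_to_nearest_focus_mm = main_to_nearest_focus_mm(foci),
    profiles = profiles,
    provenance = provenance)
  structure(report, class = "standardized_report")
}

## informational only: distance from the largest focus centroid to the
## nearest other focus centroid (NA when unifocal)
main_to_nearest_focus_mm <- function(foci) {
  if (nrow(foci) < 2L) return(NA_real_)
  cen <- as.matrix(foci[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  d <- sqrt(colSums((t(cen[-1L, , drop = FALSE]) - cen[1L, ])^2))
  min(d)
}

#' Assemble the postoperative standardized report
#'
#' Postsurgical assessment from the preoperative and postoperative tumor
#' masks: both volumes (computed on their native grids, which may
#' differ), the extent of resection, and the resection class.
#'
#' @param preop_tumor non-empty binary [label_mask].
#' @param postop_tumor binary [label_mask]; empty means complete
#'   resection.
#' @param config a [report_config()].
#' @param provenance named list stored verbatim.
#' @return A \code{standardized_report} (phase \code{"postoperative"}).
#' @export
assemble_postop_report <- function(preop_tumor, postop_tumor,
                                   config = report_config(),
                                   provenance = list()) {
  preop_ml <- mask_volume_ml(preop_tumor)
  if (preop_ml <= 0)
    stop("empty preoperative tumor mask: no postoperative report",
         call. = FALSE)
  postop_ml <- mask_volume_ml(postop_tumor)
  eor <- extent_of_resection(preop_ml, postop_ml)
  structure(list(
    phase = "postoperative",
    volumes = list(preop_ml = preop_ml, postop_ml = postop_ml),
    eor_pct = eor,
    growth_flag = eor < 0,
    resection_class = classify_resection_extent(postop_ml, eor,
                                                config$resection_thresholds),
    provenance = provenance),
    class = "standardized_report")
}

#' @export
print.standardized_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
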