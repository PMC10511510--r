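#' Dice overlap coefficient between two binary masks
#'
#' \code{100 * 2|A n B| / (|A| + |B|)}, in percent. When both masks are
#' empty the score is defined by convention (default 100), which is the
#' convention needed to credit a correct "no residual tumor" prediction
#' on tumor-free postoperative scans.
#'
#' @param gt,pred binary [label_mask] objects on the same grid.
#' @param both_empty_value value returned when both masks are empty.
#' @return Dice in percent.
#' @export
dice_coefficient <- function(gt, pred, both_empty_value = 100) {
  if (!same_geometry(gt, pred)) stop_geometry_mismatch("prediction mask")
  a <- gt$labels > 0L; b <- pred$labels > 0L
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(both_empty_value)
  100 * 2 * sum(a & b) / (na + nb)
}

#' Patient-level detection decision
#'
#' Is the prediction a patient-level true positive? Default rule: the
#' tumor counts as detected when prediction and ground truth overlap at
#' all (Dice > 0); a stricter minimum Dice can be configured. For a
#' tumor-free patient (empty ground truth) the function returns whether
#' the patient is correctly called negative is handled by
#' [cohort_patient_metrics()]; here an empty ground truth yields
#' \code{FALSE} (nothing to detect).
#'
#' @param gt,pred binary [label_mask] objects on the same grid.
#' @param min_dice_pct detection threshold on Dice, default 0 (any
#'   overlap).
#' @export
patient_detection <- function(gt, pred, min_dice_pct = 0) {
  if (!same_geometry(gt, pred)) stop_geometry_mismatch("prediction mask")
  if (sum(gt$labels > 0L) == 0L) return(FALSE)
  dice_coefficient(gt, pred, both_empty_value = 0) > min_dice_pct
}

#' Object-wise (lesion-wise) detection metrics for one patient
#'
#' Connected components of ground truth and prediction are matched: a
#' ground-truth object is recalled when some predicted component overlaps
#' it (by at least one voxel under the default rule, or with a per-pair
#' Dice above \code{match_min_dice_pct}); a predicted component is a
#' precision hit when it overlaps some ground-truth object. Recall is
#' over ground-truth objects, precision over predicted objects, F1 their
#' harmonic mean. Metrics with empty denominators are \code{NA}.
#'
#' @param gt,pred binary [label_mask] objects on the same grid.
#' @param connectivity component connectivity: 6, 18 or 26.
#' @param match_min_dice_pct per-pair Dice threshold for a match;
#'   default 0 = any voxel overlap.
#' @return List: \code{recall_pct}, \code{precision_pct}, \code{f1_pct},
#'   \code{n_gt_objects}, \code{n_pred_objects}.
#' @export
objectwise_metrics <- function(gt, pred, connectivity = 26L,
                               match_min_dice_pct = 0) {
  if (!same_geometry(gt, pred)) stop_geometry_mismatch("prediction mask")
  gl <- label_components(gt$labels, connectivity)
  pl <- label_components(pred$labels, connectivity)
  ng <- max(gl); np <- max(pl)
  pair_match <- function(gi, pj) {
    inter <- sum(gl == gi & pl == pj)
    if (inter == 0L) return(FALSE)
    if (match_min_dice_pct <= 0) return(TRUE)
    100 * 2 * inter / (sum(gl == gi) + sum(pl == pj)) > match_min_dice_pct
  }
  recalled <- if (ng > 0L) vapply(seq_len(ng), function(gi)
    any(vapply(seq_len(max(np, 0L)), function(pj) pair_match(gi, pj),
               logical(1))), logical(1)) else logical(0)
  hits <- if (np > 0L) vapply(seq_len(np), function(pj)
    any(vapply(seq_len(max(ng, 0L)), function(gi) pair_match(gi, pj),
               logical(1))), logical(1)) else logical(0)
  recall <- if (ng > 0L) 100 * sum(recalled) / ng else NA_real_
  precision <- if (np > 0L) 100 * sum(hits) / np else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision)
  else if (!is.na(recall) && !is.na(precision)) 0 else NA_real_
  list(recall_pct = recall, precision_pct = precision, f1_pct = f1,
       n_gt_objects = ng, n_pred_objects = np)
}

#' Evaluate one patient's segmentation
#'
#' Combines voxel-wise Dice, the patient-level detection decision, and
#' object-wise metrics into one row of a cohort metrics table.
#'
#' @param patient_id identifier stored in the row.
#' @param gt,pred binary [label_mask] objects on the same grid.
#' @param connectivity component connectivity.
#' @param detection_min_dice_pct patient-wise detection rule threshold.
#' @param match_min_dice_pct object-wise match rule threshold.
#' @param fold_id optional cross-validation fold label.
#' @return One-row data.frame (see [cohort_patient_metrics()]).
#' @export
evaluate_patient <- function(patient_id, gt, pred, connectivity = 26L,
                             detection_min_dice_pct = 0,
                             match_min_dice_pct = 0, fold_id = NA) {
  ow <- objectwise_metrics(gt, pred, connectivity, match_min_dice_pct)
  data.frame(patient_id = as.character(patient_id),
             fold_id = fold_id,
             dice_pct = dice_coefficient(gt, pred),
             gt_volume_ml = mask_volume_ml(gt),
             pred_volume_ml = mask_volume_ml(pred),
             detected = patient_detection(gt, pred, detection_min_dice_pct),
             object_recall_pct = ow$recall_pct,
             object_precision_pct = ow$precision_pct,
             object_f1_pct = ow$f1_pct,
             n_gt_objects = ow$n_gt_objects,
             n_pred_objects = ow$n_pred_objects,
             stringsAsFactors = FALSE)
}

#' Patient-wise cohort metrics
#'
#' Contingency over patients: a tumor patient (non-empty ground truth)
#' is a true positive when detected and a false negative otherwise; a
#' tumor-free patient is a false positive when the prediction is
#' non-empty and a true negative otherwise. Recall, precision and F1 are
#' reported in percent; Dice is averaged over all patients and, as
#' Dice-TP, over detected patients only. Metrics whose denominator is
#' zero are reported as \code{NA} (undefined), never as 0.
#'
#' @param results data.frame of [evaluate_patient()] rows.
#' @return List of cohort metrics plus the TP/FP/FN/TN counts.
#' @export
cohort_patient_metrics <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("'results' must be a non-empty data.frame", call. = FALSE)
  has_gt <- results$gt_volume_ml > 0
  has_pred <- results$pred_volume_ml > 0
  tp <- sum(has_gt & results$detected)
  fn <- sum(has_gt & !results$detected)
  fp <- sum(!has_gt & has_pred)
  tn <- sum(!has_gt & !has_pred)
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  recall <- frac(tp, tp + fn)
  precision <- frac(tp, tp + fp)
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  dice_tp <- results$dice_pct[has_gt & results$detected]
  list(recall_pct = recall, precision_pct = precision, f1_pct = f1,
       dice_mean = mean(results$dice_pct),
       dice_sd = stats::sd(results$dice_pct),
       dice_tp_mean = if (length(dice_tp)) mean(dice_tp) else NA_real_,
       dice_tp_sd = if (length(dice_tp) > 1L) stats::sd(dice_tp) else NA_real_,
       n = nrow(results), tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Stratify a cohort metrics table by tumor volume
#'
#' Labels each patient \code{"small"} when the ground-truth volume is
#' below the cut-off and \code{"non-small"} otherwise (the 2 ml cut-off
#' is the usual choice; 5 ml suits diffuse lower-grade gliomas whose
#' average volume is larger), then recomputes the patient-wise cohort
#' metrics per stratum.
#'
#' @param results data.frame of [evaluate_patient()] rows.
#' @param cutoff_ml volume cut-off in ml (default 2).
#' @return List with the annotated \code{rows} (new \code{stratum}
#'   column), per-stratum \code{counts}, and per-stratum \code{pooled}
#'   metrics (\code{NULL} with a flag when a stratum is empty).
#' @export
stratify_by_volume <- function(results, cutoff_ml = 2) {
  rows <- results
  rows$stratum <- ifelse(rows$gt_volume_ml < cutoff_ml, "small", "non-small")
  strata <- c("small", "non-small")
  counts <- stats::setNames(vapply(strata, function(s)
    sum(rows$stratum == s), integer(1)), strata)
  pooled <- stats::setNames(lapply(strata, function(s) {
    sub <- rows[rows$stratum == s, , drop = FALSE]
    if (nrow(sub) == 0L) NULL else cohort_patient_metrics(sub)
  }), strata)
  list(rows = rows, cutoff_ml = cutoff_ml, counts = counts, pooled = pooled,
       empty_strata = strata[counts == 0L])
}

#' Pool per-fold mean/sd estimates across cross-validation folds
#'
#' Pooled mean is the size-weighted mean of fold means. The pooled
#' standard deviation combines within-fold variance and the dispersion
#' of fold means around the pooled mean through the total sum of
#' squares, so that pooling any partition of a cohort — including
#' single-patient folds, whose sd may be \code{NA} — reproduces the
#' mean and (n-1)-denominator sd of the concatenated cohort exactly.
#'
#' @param per_fold data.frame with columns \code{n}, \code{mean},
#'   \code{sd} (sd may be NA for folds of size 1).
#' @return List with \code{mean}, \code{sd}, \code{n}.
#' @export
pool_fold_estimates <- function(per_fold) {
  if (is.list(per_fold) && !is.data.frame(per_fold))
    per_fold <- do.call(rbind, lapply(per_fold, as.data.frame))
  if (!is.data.frame(per_fold) || nrow(per_fold) == 0L)
    stop("'per_fold' must be a non-empty data.frame", call. = FALSE)
  if (any(per_fold$n < 1L)) stop("fold sizes must be >= 1", call. = FALSE)
  n <- per_fold$n; m <- per_fold$mean; s <- per_fold$sd
  s[is.na(s) & n == 1L] <- 0
  if (any(is.na(s) | is.na(m)))
    stop("fold means/sds must be present (sd may be NA only for n = 1)",
         call. = FALSE)
  N <- sum(n)
  M <- sum(n * m) / N
  ss_within <- sum((n - 1) * s^2)
  ss_between <- sum(n * (m - M)^2)
  sd <- if (N > 1L) sqrt((ss_within + ss_between) / (N - 1)) else NA_real_
  list(mean = M, sd = sd, n = N)
}

#' Per-fold summaries of a metric column
#'
#' @param results data.frame of [evaluate_patient()] rows with a
#'   \code{fold_id} column.
#' @param metric column name to summarize.
#' @return data.frame with one row per fold: \code{fold_id}, \code{n},
#'   \code{mean}, \code{sd}.
#' @export
fold_summaries <- function(results, metric = "dice_pct") {
  folds <- unique(results$fold_id)
  do.call(rbind, lapply(folds, function(f) {
    x <- results[results$fold_id == f, metric]
    data.frame(fold_id = f, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
  }))
}

#' Write a cohort metrics table with a pooled summary block
#'
#' One CSV row per patient followed by pooled mean +/- sd rows per
#' metric and stratum.
#'
#' @param results data.frame of [evaluate_patient()] rows.
#' @param path output CSV path.
#' @param cutoff_ml volume stratification cut-off, ml.
#' @export
write_cohort_metrics_csv <- function(results, path, cutoff_ml = 2) {
  strat <- stratify_by_volume(results, cutoff_ml)
  utils::write.csv(strat$rows, path, row.names = FALSE)
  summ <- do.call(rbind, lapply(c("all", names(strat$pooled)), function(s) {
    m <- if (s == "all") cohort_patient_metrics(results) else strat$pooled[[s]]
    if (is.null(m)) return(NULL)
    data.frame(stratum = s, n = m$n, recall_pct = m$recall_pct,
               precision_pct = m$precision_pct, f1_pct = m$f1_pct,
               dice_mean = m$dice_mean, dice_sd = m$dice_sd,
               dice_tp_mean = m$dice_tp_mean, dice_tp_sd = m$dice_tp_sd)
  }))
  summary_path <- sub("\\.csv$", "_summary.csv", path)
  utils::write.csv(summ, summary_path, row.names = FALSE)
  invisible(c(path, summary_path))
}
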