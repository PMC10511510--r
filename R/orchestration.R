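#' Run configuration
#'
#' Everything a single-patient or batch run needs: the task, the
#' preprocessing chain, inference settings, the predictor plug-in, the
#' atlas, reporting and evaluation thresholds, and the seed. A
#' content-based hash of the serializable settings is stored in every
#' report's provenance block, so identical configurations are provably
#' identical across runs.
#'
#' @param task \code{"segment"}, \code{"report_preop"},
#'   \code{"report_postop"} or \code{"evaluate"}.
#' @param preprocessing a [preprocessing_config()].
#' @param inference list: \code{patch_shape}, \code{min_overlap_fraction},
#'   \code{fusion}, \code{threshold} (binarization),
#'   \code{brain_working_shape}, \code{brain_threshold}.
#' @param predictor a [predictor]; only its name enters the hash.
#' @param atlas an [atlas_bundle], or \code{NULL} with \code{atlas_path}.
#' @param atlas_path directory readable by [read_atlas_bundle()].
#' @param report a [report_config()].
#' @param evaluation list: \code{detection_min_dice_pct},
#'   \code{match_min_dice_pct}, \code{connectivity},
#'   \code{volume_cutoff_ml}.
#' @param skip_segmentation use user-supplied masks instead of running
#'   inference (reports from manual delineations).
#' @param seed integer seed recorded in provenance.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @export
run_config <- function(task = c("report_preop", "report_postop", "segment",
                                "evaluate"),
                       preprocessing = preprocessing_config(),
                       inference = list(),
                       predictor = make_threshold_predictor(0.75),
                       atlas = NULL, atlas_path = NULL,
                       report = report_config(),
                       evaluation = list(),
                       skip_segmentation = FALSE,
                       seed = 42L, log_level = c("info", "quiet")) {
  task <- match.arg(task)
  log_level <- match.arg(log_level)
  inf_defaults <- list(patch_shape = c(160L, 160L, 160L),
                       min_overlap_fraction = 0, fusion = "mean",
                       threshold = 0.5,
                       brain_working_shape = c(32L, 32L, 32L),
                       brain_threshold = 0.5)
  unknown <- setdiff(names(inference), names(inf_defaults))
  if (length(unknown))
    stop("unknown inference settings: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  inference <- utils::modifyList(inf_defaults, inference)
  ev_defaults <- list(detection_min_dice_pct = 0, match_min_dice_pct = 0,
                      connectivity = 26L, volume_cutoff_ml = 2)
  unknown <- setdiff(names(evaluation), names(ev_defaults))
  if (length(unknown))
    stop("unknown evaluation settings: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  evaluation <- utils::modifyList(ev_defaults, evaluation)
  if (is.null(atlas) && !is.null(atlas_path))
    atlas <- read_atlas_bundle(atlas_path)
  cfg <- structure(list(task = task, preprocessing = preprocessing,
                        inference = inference, predictor = predictor,
                        atlas = atlas, report = report,
                        evaluation = evaluation,
                        skip_segmentation = isTRUE(skip_segmentation),
                        seed = as.integer(seed), log_level = log_level),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

## content hash over the serializable settings (predictor by name only)
config_hash <- function(config) {
  ser <- list(task = config$task,
              preprocessing = unclass(config$preprocessing),
              inference = config$inference,
              predictor = config$predictor$name,
              report = unclass(config$report),
              evaluation = config$evaluation,
              skip_segmentation = config$skip_segmentation,
              seed = config$seed)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Parse a run configuration from a JSON file
#'
#' Schema-validated: unknown top-level keys are rejected. The predictor
#' is described by \code{predictor_threshold} (a voxel-local threshold
#' predictor); external predictors must be constructed in code.
#'
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("task", "preprocessing", "inference", "predictor_threshold",
             "atlas_path", "report", "evaluation", "skip_segmentation",
             "seed", "log_level")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pre <- do.call(preprocessing_config, as.list(x$preprocessing))
  rep_cfg <- if (is.null(x$report)) report_config()
             else do.call(report_config, as.list(x$report))
  run_config(task = x$task %||% "report_preop", preprocessing = pre,
             inference = as.list(x$inference),
             predictor = make_threshold_predictor(x$predictor_threshold %||% 0.75),
             atlas_path = x$atlas_path, report = rep_cfg,
             evaluation = as.list(x$evaluation),
             skip_segmentation = isTRUE(x$skip_segmentation),
             seed = x$seed %||% 42L,
             log_level = x$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(config, ..., logfile = NULL) {
  line <- paste0(...)
  if (!identical(config$log_level, "quiet")) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

volume_file_pattern <- "\\.(nii|nii\\.gz|mhd|mha|nrrd|nhdr)$"

mask_kind_from_name <- function(path) {
  base <- basename(path)
  if (grepl("brain", base, ignore.case = TRUE)) "brain" else "tumor"
}

#' Load a patient folder into a patient record
#'
#' Timestamp subfolders (\code{T0}, \code{T1}, ...) are mapped in
#' ascending order; a flat folder becomes a single timestamp \code{T0}.
#' Files whose name contains \code{label} or \code{annotation} are
#' treated as masks and linked to the unique image with matching volume
#' parameters (shape, spacing, orientation); ambiguous or impossible
#' linkage is an error demanding an explicit mapping.
#'
#' @param folder_path patient directory.
#' @return A \code{patient_record}: \code{patient_id}, \code{timestamps}
#'   (each with \code{label}, \code{images}, \code{masks}),
#'   \code{source_dir}.
#' @export
load_patient_record <- function(folder_path) {
  if (!dir.exists(folder_path))
    stop("no such patient folder: ", folder_path, call. = FALSE)
  subs <- list.dirs(folder_path, recursive = FALSE)
  ts_dirs <- subs[grepl("^T[0-9]+$", basename(subs))]
  ts_dirs <- ts_dirs[order(as.integer(sub("^T", "", basename(ts_dirs))))]
  if (length(ts_dirs) == 0L) ts_dirs <- folder_path
  timestamps <- lapply(seq_along(ts_dirs), function(i) {
    d <- ts_dirs[i]
    label <- if (identical(d, folder_path)) "T0" else basename(d)
    files <- list.files(d, pattern = volume_file_pattern, full.names = TRUE)
    is_mask <- grepl("label|annotation", basename(files), ignore.case = TRUE)
    images <- files[!is_mask]
    masks <- files[is_mask]
    if (length(masks) && length(images) == 0L)
      stop("masks present but no image in ", d, call. = FALSE)
    img_objs <- lapply(images, read_volume)
    mask_links <- lapply(masks, function(mp) {
      m <- read_volume(mp)
      matches <- which(vapply(img_objs, function(im) same_geometry(im, m),
                              logical(1)))
      if (length(matches) == 0L)
        stop("annotation ", basename(mp), " matches no image geometry ",
             "(shape/spacing/orientation must match)", call. = FALSE)
      if (length(matches) > 1L && length(unique(images[matches])) > 1L)
        stop("annotation ", basename(mp), " matches several images; ",
             "explicit parent mapping required", call. = FALSE)
      list(path = mp, kind = mask_kind_from_name(mp),
           parent_image = images[matches[1L]])
    })
    list(label = label, images = images, masks = mask_links)
  })
  structure(list(patient_id = basename(normalizePath(folder_path)),
                 timestamps = timestamps,
                 source_dir = folder_path),
            class = "patient_record")
}

find_mask <- function(ts, kind) {
  for (m in ts$masks) if (identical(m$kind, kind)) return(m)
  NULL
}

#' Segment one volume with the configured pipeline
#'
#' Preprocess (isotropic resampling, optional skull-stripping, clipping
#' and normalization), run patch-wise inference with the configured
#' predictor, binarize, and bring the mask back onto the native grid.
#' When no brain mask is supplied and skull-stripping is requested, the
#' brain is first segmented in fast single-shot mode over a downsampled
#' copy of the scan.
#'
#' @param image native-grid [volumetric_image].
#' @param config a [run_config()].
#' @param brain optional brain [label_mask] on the native grid.
#' @return Binary tumor [label_mask] on the native grid.
#' @export
segment_image <- function(image, config, brain = NULL) {
  if (is.null(brain) && config$preprocessing$skull_strip) {
    norm <- clip_and_normalize(image, config$preprocessing$clip_upper_fraction,
                               config$preprocessing$normalization_range)
    brain <- predict_downsampled(norm, config$predictor,
                                 config$inference$brain_working_shape,
                                 config$inference$brain_threshold)
  }
  pp <- preprocess_image(image, config$preprocessing, brain)
  grid <- plan_patch_grid(image_shape(pp$image), config$inference$patch_shape,
                          config$inference$min_overlap_fraction)
  prob <- predict_patchwise(pp$image, config$predictor, grid,
                            config$inference$fusion)
  iso_mask <- binarize_probability(prob, config$inference$threshold, "tumor")
  native_labels <- resample_array(iso_mask$labels, geom_spacing(iso_mask),
                                  image_shape(image), geom_spacing(image),
                                  "nearest")
  label_mask(native_labels, image, kind = "tumor")
}

tumor_mask_for_timestamp <- function(ts, config) {
  image <- read_volume(ts$images[[1L]])
  tm <- find_mask(ts, "tumor")
  bm <- find_mask(ts, "brain")
  brain <- if (!is.null(bm)) read_mask(bm$path, "brain") else NULL
  if (config$skip_segmentation && !is.null(tm)) {
    mask <- read_mask(tm$path, "tumor")
    src <- basename(tm$path)
  } else {
    mask <- segment_image(image, config, brain)
    src <- paste0("segmented:", config$predictor$name)
  }
  list(image = image, mask = mask, source = src,
       image_file = basename(ts$images[[1L]]))
}

#' Run the configured task for one patient
#'
#' Executes preprocess, (optional) inference, registration and report
#' assembly for the record's timestamps, writing NIfTI masks, the
#' serialized reports and a plain-text run log under
#' \code{output_dir/<patient_id>/}. Deterministic given the
#' configuration: re-running produces byte-identical reports.
#'
#' @param record a [load_patient_record()] result.
#' @param config a [run_config()]; \code{task = "report_postop"} needs
#'   two timestamps.
#' @param output_dir output root.
#' @return List with the written \code{report} (when the task produces
#'   one), \code{paths} of the outputs, and the native-grid masks.
#' @export
run_single_patient <- function(record, config, output_dir) {
  pdir <- file.path(output_dir, record$patient_id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(pdir, "run.log")
  cat("task=", config$task, " config=", config$hash, "\n", sep = "",
      file = logfile)
  paths <- character()
  note <- function(p) { cat("wrote ", p, "\n", sep = "", file = logfile,
                            append = TRUE); paths <<- c(paths, p) }
  provenance <- function(extra) c(list(patient_id = record$patient_id,
                                       config_hash = config$hash,
                                       seed = config$seed), extra)
  result <- list()
  if (config$task %in% c("segment", "report_preop", "evaluate")) {
    ts0 <- record$timestamps[[1L]]
    t0 <- tumor_mask_for_timestamp(ts0, config)
    mp <- file.path(pdir, "predicted_tumor_T0.nii.gz")
    write_volume(t0$mask, mp); note(mp)
    result$tumor_t0 <- t0$mask
    if (config$task == "report_preop") {
      atlas <- config$atlas
      if (is.null(atlas))
        stop("report_preop requires an atlas bundle in the configuration",
             call. = FALSE)
      tf <- estimate_transform(t0$image, atlas$reference)
      tumor_ref <- warp_mask(t0$mask, tf, atlas$reference)
      tp <- file.path(pdir, "transform_T0_to_atlas.json")
      write_transform(tf, tp); note(tp)
      wp <- file.path(pdir, "tumor_atlas_space.nii.gz")
      write_volume(tumor_ref, wp); note(wp)
      report <- assemble_preop_report(
        t0$mask, tumor_ref, atlas, config$report,
        provenance(list(timestamp = ts0$label, image_file = t0$image_file,
                        tumor_source = t0$source)))
      note_paths <- serialize_report(report, pdir)
      for (p in note_paths) note(p)
      result$report <- report
    }
  }
  if (config$task == "report_postop") {
    if (length(record$timestamps) < 2L)
      stop("postoperative report requires two timestamps (preop, postop)",
           call. = FALSE)
    t0 <- tumor_mask_for_timestamp(record$timestamps[[1L]], config)
    t1 <- tumor_mask_for_timestamp(record$timestamps[[2L]], config)
    for (pair in list(list(t0, "T0"), list(t1, "T1"))) {
      mp <- file.path(pdir, sprintf("predicted_tumor_%s.nii.gz", pair[[2L]]))
      write_volume(pair[[1L]]$mask, mp); note(mp)
    }
    report <- assemble_postop_report(
      t0$mask, t1$mask, config$report,
      provenance(list(timestamps = c(record$timestamps[[1L]]$label,
                                     record$timestamps[[2L]]$label),
                      image_files = c(t0$image_file, t1$image_file),
                      tumor_sources = c(t0$source, t1$source))))
    note_paths <- serialize_report(report, pdir)
    for (p in note_paths) note(p)
    result$report <- report
    result$tumor_t0 <- t0$mask
    result$tumor_t1 <- t1$mask
  }
  if (config$task == "evaluate") {
    ts0 <- record$timestamps[[1L]]
    tm <- find_mask(ts0, "tumor")
    if (is.null(tm))
      stop("evaluate task requires a ground-truth tumor mask", call. = FALSE)
    gt <- read_mask(tm$path, "tumor")
    result$eval_row <- evaluate_patient(
      record$patient_id, gt, result$tumor_t0,
      connectivity = config$evaluation$connectivity,
      detection_min_dice_pct = config$evaluation$detection_min_dice_pct,
      match_min_dice_pct = config$evaluation$match_min_dice_pct)
  }
  result$paths <- paths
  log_msg(config, "[", record$patient_id, "] ", config$task, " done (",
          length(paths), " files)", logfile = NULL)
  result
}

#' Sequential batch run over a cohort folder
#'
#' Each immediate subfolder of \code{cohort_dir} is one patient.
#' Patients are processed sequentially; a failure is logged and isolated
#' so the run continues. Cohort-level summary CSVs are written: a
#' content listing, a feature table (flattened report values, one row
#' per patient), and — for the evaluate task — the cohort metrics table
#' with its pooled summary block.
#'
#' @param cohort_dir directory of patient folders.
#' @param config a [run_config()].
#' @param output_dir output root.
#' @return List: per-patient \code{results}, \code{failures} (named
#'   error messages), \code{summary_paths}, and \code{status} (0 all
#'   succeeded, 2 partial failure).
#' @export
run_batch <- function(cohort_dir, config, output_dir) {
  pdirs <- list.dirs(cohort_dir, recursive = FALSE)
  pdirs <- pdirs[dir.exists(pdirs)]
  if (length(pdirs) == 0L)
    stop("empty cohort: no patient folders in ", cohort_dir, call. = FALSE)
  results <- list(); failures <- character()
  for (d in pdirs) {
    pid <- basename(d)
    res <- tryCatch({
      rec <- load_patient_record(d)
      run_single_patient(rec, config, output_dir)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[pid] <- conditionMessage(res)
      log_msg(config, "[", pid, "] FAILED: ", conditionMessage(res))
    } else results[[pid]] <- res
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  summary_paths <- character()
  content <- do.call(rbind, lapply(pdirs, function(d) {
    files <- list.files(d, recursive = TRUE)
    if (length(files) == 0L) return(NULL)
    data.frame(patient_id = basename(d), file = files)
  }))
  cp <- file.path(output_dir, "cohort_contents.csv")
  utils::write.csv(content, cp, row.names = FALSE)
  summary_paths <- c(summary_paths, cp)
  reports <- Filter(Negate(is.null), lapply(results, `[[`, "report"))
  if (length(reports)) {
    feat <- do.call(rbind, lapply(names(reports), function(pid) {
      fl <- flatten_report(reports[[pid]])
      cbind(patient_id = pid, fl)
    }))
    fp <- file.path(output_dir, "cohort_features.csv")
    utils::write.csv(feat, fp, row.names = FALSE)
    summary_paths <- c(summary_paths, fp)
  }
  eval_rows <- Filter(Negate(is.null), lapply(results, `[[`, "eval_row"))
  if (length(eval_rows)) {
    tab <- do.call(rbind, eval_rows)
    ep <- file.path(output_dir, "cohort_metrics.csv")
    write_cohort_metrics_csv(tab, ep, config$evaluation$volume_cutoff_ml)
    summary_paths <- c(summary_paths, ep,
                       sub("\\.csv$", "_summary.csv", ep))
  }
  list(results = results, failures = failures,
       summary_paths = summary_paths,
       status = if (length(failures) == 0L) 0L else 2L)
}
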