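## shared fixtures: one small cohort and a toy atlas, built once per file
local_cohort <- local({
  d <- file.path(tempdir(), "orch_cohort")
  if (!dir.exists(d)) make_synthetic_cohort(3, seed = 21, out_dir = d)
  d
})
local_manifest <- jsonlite::read_json(file.path(local_cohort, "manifest.json"),
                                      simplifyVector = FALSE)
local_atlas <- make_toy_atlas(
  make_head_phantom(phantom_spec(shape = c(40, 40, 40),
                                 spacing_mm = c(1.2, 1.2, 1.2), seed = 99,
                                 noise_sd = 0)), 4)

test_that("patient folders load with timestamps in ascending order", {
  rec <- load_patient_record(file.path(local_cohort, "patient_001"))
  expect_identical(vapply(rec$timestamps, `[[`, "", "label"), c("T0", "T1"))
  expect_identical(length(rec$timestamps[[1]]$images), 1L)
  kinds <- vapply(rec$timestamps[[1]]$masks, `[[`, "", "kind")
  expect_setequal(kinds, c("tumor", "brain"))
  # each mask linked to the single geometry-matching image
  for (m in rec$timestamps[[1]]$masks)
    expect_identical(m$parent_image, rec$timestamps[[1]]$images[[1]])
})

test_that("flat folders and linkage failures follow the import rules", {
  flat <- tempfile(); dir.create(flat)
  img <- volumetric_image(array(stats::runif(8^3), c(8, 8, 8)))
  write_volume(img, file.path(flat, "scan.nii.gz"))
  rec <- load_patient_record(flat)
  expect_identical(length(rec$timestamps), 1L)
  expect_identical(rec$timestamps[[1]]$label, "T0")

  # a mask whose shape matches no image must be rejected
  write_volume(mask_on(array(1, c(6, 6, 6)), grid_image(c(6, 6, 6))),
               file.path(flat, "label_tumor.nii.gz"))
  expect_error(load_patient_record(flat), "matches no image")
  expect_error(load_patient_record(tempfile()), "no such patient folder")
})

test_that("report serialization round-trips and flattens consistently", {
  rec <- load_patient_record(file.path(local_cohort, "patient_002"))
  cfg <- run_config("report_postop", skip_segmentation = TRUE,
                    log_level = "quiet")
  res <- run_single_patient(rec, cfg, tempfile())
  report <- res$report

  out <- tempfile()
  paths <- serialize_report(report, out)
  expect_identical(length(paths), 3L)
  back <- read_report_json(file.path(out, "report_postoperative.json"))
  expect_equal(back$volumes$preop_ml, report$volumes$preop_ml)
  expect_equal(back$eor_pct, report$eor_pct)
  expect_identical(back$resection_class, report$resection_class)

  flat <- flatten_report(report)
  csv <- read.csv(file.path(out, "report_postoperative.csv"))
  expect_identical(nrow(csv), nrow(flat))
  expect_warning(serialize_report(report, out, formats = character()),
                 "nothing written")
})

test_that("preoperative pipeline volumes match the generator manifest", {
  cfg <- run_config("report_preop", atlas = local_atlas,
                    skip_segmentation = TRUE, log_level = "quiet")
  for (pid in c("patient_001", "patient_002")) {
    rec <- load_patient_record(file.path(local_cohort, pid))
    res <- run_single_patient(rec, cfg, tempfile())
    p <- local_manifest$patients[[pid]]
    expect_equal(res$report$volumes$patient_space_ml, p$preop_voxel_ml,
                 tolerance = 1e-12)
    gt <- read_mask(file.path(local_cohort, pid, "T0", "label_tumor.nii.gz"))
    shell <- oracle_surface_voxels(gt$labels) * voxel_volume_mm3(gt) / 1000
    expect_lt(abs(res$report$volumes$patient_space_ml - p$preop_analytic_ml),
              shell)
    expect_identical(res$report$multifocal, p$n_preop_foci >= 2)
    for (prof in res$report$profiles)
      expect_equal(sum(unlist(prof)), 100, tolerance = 1e-6)
  }
})

test_that("segmentation-backed run recovers the ground-truth tumor", {
  rec <- load_patient_record(file.path(local_cohort, "patient_003"))
  cfg <- run_config("segment",
                    preprocessing = preprocessing_config(target_spacing_mm = 1),
                    inference = list(patch_shape = c(32L, 32L, 32L)),
                    predictor = make_threshold_predictor(0.8),
                    log_level = "quiet")
  res <- run_single_patient(rec, cfg, tempfile())
  gt <- read_mask(file.path(local_cohort, "patient_003", "T0",
                            "label_tumor.nii.gz"))
  expect_gt(dice_coefficient(gt, res$tumor_t0), 95)
})

test_that("runs are deterministic: repeated runs give byte-identical reports", {
  rec <- load_patient_record(file.path(local_cohort, "patient_002"))
  cfg <- run_config("report_postop", skip_segmentation = TRUE,
                    log_level = "quiet")
  o1 <- tempfile(); o2 <- tempfile()
  run_single_patient(rec, cfg, o1)
  run_single_patient(rec, cfg, o2)
  j1 <- file.path(o1, "patient_002", "report_postoperative.json")
  j2 <- file.path(o2, "patient_002", "report_postoperative.json")
  expect_identical(readLines(j1), readLines(j2))
})

test_that("batch runs equal the set of single-patient runs and isolate failures", {
  cfg <- run_config("report_postop", skip_segmentation = TRUE,
                    log_level = "quiet")
  bdir <- tempfile()
  batch <- run_batch(local_cohort, cfg, bdir)
  expect_identical(batch$status, 0L)
  expect_identical(length(batch$results), 3L)
  feat <- read.csv(file.path(bdir, "cohort_features.csv"))
  expect_identical(length(unique(feat$patient_id)), 3L)
  expect_true(file.exists(file.path(bdir, "cohort_contents.csv")))

  # batch output matches the corresponding single runs byte for byte
  sdir <- tempfile()
  for (pid in names(batch$results)) {
    rec <- load_patient_record(file.path(local_cohort, pid))
    run_single_patient(rec, cfg, sdir)
    expect_identical(
      readLines(file.path(bdir, pid, "report_postoperative.json")),
      readLines(file.path(sdir, pid, "report_postoperative.json")))
  }

  # one corrupt patient folder: the others still succeed, status = partial
  broken <- tempfile(); dir.create(broken)
  file.copy(file.path(local_cohort, c("patient_001", "patient_002")),
            broken, recursive = TRUE)
  bad <- file.path(broken, "patient_bad", "T0"); dir.create(bad,
                                                            recursive = TRUE)
  writeLines("not a nifti", file.path(bad, "image.nii"))
  res <- suppressWarnings(suppressMessages(run_batch(broken, cfg, tempfile())))
  expect_identical(length(res$results), 2L)
  expect_identical(names(res$failures), "patient_bad")
  expect_identical(res$status, 2L)
  expect_error(run_batch(tempfile(), cfg, tempfile()), "empty cohort")
})

test_that("evaluate task produces a cohort metrics table", {
  cfg <- run_config("evaluate",
                    preprocessing = preprocessing_config(target_spacing_mm = 1),
                    inference = list(patch_shape = c(32L, 32L, 32L)),
                    predictor = make_threshold_predictor(0.8),
                    log_level = "quiet")
  bdir <- tempfile()
  batch <- run_batch(local_cohort, cfg, bdir)
  expect_identical(batch$status, 0L)
  tab <- read.csv(file.path(bdir, "cohort_metrics.csv"))
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$dice_pct > 95))
  expect_true(file.exists(file.path(bdir, "cohort_metrics_summary.csv")))
})

test_that("configuration is schema-validated with a stable content hash", {
  expect_error(run_config(inference = list(bogus = 1)), "unknown inference")
  expect_error(run_config(evaluation = list(bogus = 1)), "unknown evaluation")
  c1 <- run_config("report_preop", log_level = "quiet")
  c2 <- run_config("report_preop", log_level = "quiet")
  expect_identical(c1$hash, c2$hash)
  c3 <- run_config("report_preop", seed = 7L, log_level = "quiet")
  expect_false(identical(c1$hash, c3$hash))

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(task = "report_postop", seed = 9,
                            skip_segmentation = TRUE),
                       f, auto_unbox = TRUE)
  cfg <- read_run_config(f)
  expect_identical(cfg$task, "report_postop")
  expect_identical(cfg$seed, 9L)
  jsonlite::write_json(list(task = "segment", nonsense = 1), f,
                       auto_unbox = TRUE)
  expect_error(read_run_config(f), "unknown configuration")
})
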