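gridm <- function(arr, grid) mask_on(arr, grid)

test_that("Dice coefficient: exact values, symmetry, conventions", {
  grid <- grid_image(c(10, 10, 10))
  a <- array(0L, c(10, 10, 10)); a[1:3, 1, 1] <- 1L
  b <- array(0L, c(10, 10, 10)); b[5:7, 1, 1] <- 1L
  expect_equal(dice_coefficient(gridm(a, grid), gridm(a, grid)), 100)
  expect_equal(dice_coefficient(gridm(a, grid), gridm(b, grid)), 0)
  x <- array(0L, c(10, 10, 10)); x[1:2, 1, 1] <- 1L
  y <- array(0L, c(10, 10, 10)); y[2:3, 1, 1] <- 1L
  expect_equal(dice_coefficient(gridm(x, grid), gridm(y, grid)), 50)
  # symmetry over random pairs
  set.seed(61)
  for (rep in 1:5) {
    p <- random_mask_array(c(10, 10, 10)); q <- random_mask_array(c(10, 10, 10))
    expect_equal(dice_coefficient(gridm(p, grid), gridm(q, grid)),
                 dice_coefficient(gridm(q, grid), gridm(p, grid)))
  }
  z <- array(0L, c(10, 10, 10))
  expect_equal(dice_coefficient(gridm(z, grid), gridm(z, grid)), 100)
  expect_equal(dice_coefficient(gridm(z, grid), gridm(z, grid),
                                both_empty_value = 0), 0)
  other <- grid_image(c(10, 10, 10), spacing = c(2, 2, 2))
  expect_error(dice_coefficient(gridm(a, grid), gridm(a, other)), "geometry")
})

test_that("patient-level detection rule and its configurable threshold", {
  grid <- grid_image(c(12, 12, 12))
  gt <- array(0L, c(12, 12, 12)); gt[2:9, 2:9, 2:9] <- 1L
  pred_big <- array(0L, c(12, 12, 12)); pred_big[2:9, 2:9, 2:9] <- 1L
  expect_true(patient_detection(gridm(gt, grid), gridm(pred_big, grid)))
  expect_false(patient_detection(gridm(gt, grid),
                                 gridm(array(0L, c(12, 12, 12)), grid)))
  # one-voxel overlap: detected under any-overlap, not under Dice > 25%
  pred_1vox <- array(0L, c(12, 12, 12)); pred_1vox[9, 9, 9] <- 1L
  pred_1vox[10:12, 10:12, 10:12] <- 1L
  d <- oracle_dice_pct(gt, pred_1vox)
  expect_true(d > 0 && d < 25)
  expect_true(patient_detection(gridm(gt, grid), gridm(pred_1vox, grid)))
  expect_false(patient_detection(gridm(gt, grid), gridm(pred_1vox, grid),
                                 min_dice_pct = 25))
})

test_that("cohort patient metrics reproduce hand-computed contingencies", {
  rows <- data.frame(
    patient_id = c("a", "b", "c"),
    dice_pct = c(80, 60, 0), gt_volume_ml = c(5, 4, 3),
    pred_volume_ml = c(5, 4, 0), detected = c(TRUE, TRUE, FALSE))
  m <- cohort_patient_metrics(rows)
  expect_equal(m$recall_pct, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(m$dice_mean, mean(c(80, 60, 0)))
  expect_equal(m$dice_tp_mean, 70)

  rows2 <- data.frame(
    patient_id = c("a", "b", "c"),
    dice_pct = c(90, 85, 0), gt_volume_ml = c(5, 4, 0),
    pred_volume_ml = c(5, 4, 1), detected = c(TRUE, TRUE, FALSE))
  m2 <- cohort_patient_metrics(rows2)
  expect_equal(m2$precision_pct, 100 * 2 / 3, tolerance = 1e-9)
  expect_identical(m2$fp, 1L)

  perfect <- data.frame(patient_id = "a", dice_pct = 100, gt_volume_ml = 1,
                        pred_volume_ml = 1, detected = TRUE)
  mp <- cohort_patient_metrics(perfect)
  expect_equal(c(mp$recall_pct, mp$precision_pct, mp$f1_pct,
                 mp$dice_mean, mp$dice_tp_mean), rep(100, 5))

  # undefined metrics are NA, never 0
  neg_only <- data.frame(patient_id = "a", dice_pct = 100, gt_volume_ml = 0,
                         pred_volume_ml = 0, detected = FALSE)
  mn <- cohort_patient_metrics(neg_only)
  expect_true(is.na(mn$recall_pct))
  expect_true(is.na(mn$precision_pct))
})

test_that("object-wise metrics agree with the flood-fill oracle", {
  grid <- grid_image(c(16, 16, 16))
  gt <- array(0L, c(16, 16, 16))
  gt[2:5, 2:5, 2:5] <- 1L       # large focus
  gt[11:12, 11:12, 11:12] <- 1L # small focus
  covers_both <- gt
  ow <- objectwise_metrics(gridm(gt, grid), gridm(covers_both, grid))
  expect_equal(ow$recall_pct, 100)
  only_large <- array(0L, c(16, 16, 16)); only_large[2:5, 2:5, 2:5] <- 1L
  ow2 <- objectwise_metrics(gridm(gt, grid), gridm(only_large, grid))
  expect_equal(ow2$recall_pct, 50)
  expect_equal(ow2$precision_pct, 100)
  spurious <- only_large
  spurious[9:10, 2:3, 2:3] <- 1L
  spurious[14:15, 14:15, 14:15] <- 1L
  one_gt <- array(0L, c(16, 16, 16)); one_gt[2:5, 2:5, 2:5] <- 1L
  ow3 <- objectwise_metrics(gridm(one_gt, grid), gridm(spurious, grid))
  expect_equal(ow3$recall_pct, 100)
  expect_equal(ow3$precision_pct, 100 / 3, tolerance = 1e-9)

  # randomized agreement with the independent oracle
  set.seed(62)
  for (rep in 1:10) {
    g <- random_mask_array(c(14, 14, 14), p_empty = 0.15)
    p <- random_mask_array(c(14, 14, 14), p_empty = 0.15)
    got <- objectwise_metrics(gridm(g, grid_image(c(14, 14, 14))),
                              gridm(p, grid_image(c(14, 14, 14))))
    want <- oracle_objectwise(g, p)
    expect_equal(got$recall_pct, want$recall)
    expect_equal(got$precision_pct, want$precision)
    expect_identical(got$n_gt_objects, want$ng)
    expect_identical(got$n_pred_objects, want$np)
  }
})

test_that("object-wise recall reduces to patient detection for single-object patients", {
  set.seed(63)
  grid <- grid_image(c(12, 12, 12))
  for (rep in 1:5) {
    g <- array(0L, c(12, 12, 12))
    lo <- sample(1:6, 3, TRUE); g[lo[1]:(lo[1] + 4), lo[2]:(lo[2] + 4),
                                  lo[3]:(lo[3] + 4)] <- 1L
    p <- random_mask_array(c(12, 12, 12), p_empty = 0.3)
    ow <- objectwise_metrics(gridm(g, grid), gridm(p, grid))
    det <- patient_detection(gridm(g, grid), gridm(p, grid))
    expect_equal(ow$recall_pct == 100, det)
  }
})

test_that("volume stratification counts match a comparison oracle", {
  set.seed(64)
  vols <- c(runif(3, 0.1, 1.9), runif(7, 2.1, 30))
  rows <- data.frame(patient_id = paste0("p", 1:10),
                     dice_pct = runif(10, 40, 100),
                     gt_volume_ml = sample(vols),
                     pred_volume_ml = 1, detected = TRUE)
  s <- stratify_by_volume(rows, 2)
  expect_identical(unname(s$counts["small"]), sum(rows$gt_volume_ml < 2))
  expect_identical(unname(s$counts["small"]), 3L)
  expect_identical(unname(s$counts["non-small"]), 7L)
  expect_identical(sum(s$counts), nrow(rows))

  all_big <- rows; all_big$gt_volume_ml <- all_big$gt_volume_ml + 100
  s2 <- stratify_by_volume(all_big, 2)
  expect_identical(s2$empty_strata, "small")
  expect_null(s2$pooled$small)

  s5 <- stratify_by_volume(rows, 5)
  expect_identical(unname(s5$counts["small"]), sum(rows$gt_volume_ml < 5))
})

test_that("fold pooling reproduces concatenated-cohort statistics exactly", {
  pf <- data.frame(n = c(2, 2), mean = c(70, 90), sd = c(sd(c(80, 60)),
                                                         sd(c(100, 80))))
  pooled <- pool_fold_estimates(pf)
  expect_equal(pooled$mean, 80)
  expect_equal(pooled$sd, sd(c(80, 60, 100, 80)))

  ident <- data.frame(n = c(3, 3), mean = c(50, 50), sd = c(10, 10))
  pi_ <- pool_fold_estimates(ident)
  expect_equal(pi_$mean, 50)

  set.seed(65)
  x <- runif(17, 0, 100)
  singles <- data.frame(n = rep(1, 17), mean = x, sd = NA_real_)
  ps <- pool_fold_estimates(singles)
  expect_equal(ps$mean, mean(x))
  expect_equal(ps$sd, sd(x))

  # arbitrary partitions: the defining concatenation-equivalence property
  for (rep in 1:10) {
    x <- runif(sample(6:30, 1), 0, 100)
    k <- sample(1:4, 1)
    f <- sort(sample(k, length(x), TRUE))
    pf <- do.call(rbind, lapply(unique(f), function(i) {
      xi <- x[f == i]
      data.frame(n = length(xi), mean = mean(xi),
                 sd = if (length(xi) > 1) sd(xi) else NA_real_)
    }))
    pooled <- pool_fold_estimates(pf)
    expect_equal(pooled$mean, mean(x), tolerance = 1e-12)
    expect_equal(pooled$sd, sd(x), tolerance = 1e-12)
  }
  expect_error(pool_fold_estimates(data.frame(n = numeric(), mean = numeric(),
                                              sd = numeric())), "non-empty")
})

test_that("per-patient evaluation rows feed the cohort CSV writer", {
  ph <- make_head_phantom(phantom_spec(shape = c(24, 24, 24), seed = 15,
                                       noise_sd = 0))
  tu <- make_tumor(tumor_spec(list(list(center_mm = ph$brain_center_mm,
                                        radii_mm = 4))), ph)
  row <- evaluate_patient("p1", tu$mask, tu$mask, fold_id = 1)
  expect_equal(row$dice_pct, 100)
  expect_true(row$detected)
  expect_identical(row$n_gt_objects, 1L)
  rows <- rbind(row, evaluate_patient("p2", tu$mask, tu$mask, fold_id = 2))
  f <- tempfile(fileext = ".csv")
  paths <- write_cohort_metrics_csv(rows, f)
  tab <- read.csv(f)
  expect_identical(nrow(tab), 2L)
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", f)))
  fs <- fold_summaries(rows)
  expect_identical(nrow(fs), 2L)
  expect_equal(pool_fold_estimates(fs)$mean, 100)
})
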