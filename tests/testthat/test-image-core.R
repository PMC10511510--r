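test_that("isotropic resampling preserves physical extent and handles identity", {
  img <- volumetric_image(array(stats::rnorm(64^3), c(64, 64, 64)),
                          spacing = c(1.5, 1.5, 1.5))
  iso <- resample_to_isotropic(img, 0.75)
  expect_equal(iso$spacing, c(0.75, 0.75, 0.75))
  expect_identical(image_shape(iso), c(128L, 128L, 128L))
  # extent oracle per axis: 64 * 1.5 == 128 * 0.75
  expect_equal(image_shape(iso) * iso$spacing, image_shape(img) * img$spacing)

  same <- volumetric_image(array(stats::runif(64^3), c(64, 64, 64)),
                           spacing = c(0.75, 0.75, 0.75))
  out <- resample_to_isotropic(same, 0.75)
  expect_identical(image_shape(out), image_shape(same))
  expect_equal(out$voxels, same$voxels)

  expect_error(resample_to_isotropic(img, -1), "positive")
  expect_error(resample_to_isotropic(img, 0), "positive")
})

test_that("resampling round-trip recovers the original shape", {
  set.seed(11)
  img <- volumetric_image(array(stats::runif(40 * 32 * 24), c(40, 32, 24)),
                          spacing = c(1.5, 1.5, 1.5))
  back <- resample_to_isotropic(resample_to_isotropic(img, 0.75), 1.5)
  expect_identical(image_shape(back), image_shape(img))
  # interpolation error exists but should be modest for smooth-ish data
  expect_lt(mean(abs(back$voxels - img$voxels)), 0.5)
})

test_that("nearest-neighbor resampling never invents labels", {
  set.seed(21)
  for (rep in 1:5) {
    labs <- array(sample(c(0L, 0L, 1L, 3L, 7L), 20^3, TRUE), c(20, 20, 20))
    grid <- grid_image(c(20, 20, 20), spacing = runif(3, 0.5, 2))
    m <- label_mask(labs, grid, kind = "parcellation")
    res <- resample_to_isotropic(m, runif(1, 0.4, 2.5), "nearest")
    expect_true(all(unique(as.vector(res$labels)) %in% unique(as.vector(labs))))
  }
  m <- mask_on(array(1, c(8, 8, 8)), grid_image(c(8, 8, 8)))
  expect_error(resample_to_isotropic(m, 0.5, "linear"), "nearest")
})

test_that("intensity clipping matches a full-sort quantile oracle", {
  set.seed(5)
  vals <- seq(0, 1, length.out = 10000)
  vals[1234] <- 50  # one extreme outlier
  img <- volumetric_image(array(sample(vals), c(10, 10, 100)))
  clipped <- clip_and_normalize(img, clip_upper_fraction = 0.0005,
                                range = c(0, 1))
  # oracle: after clipping at the 99.95th percentile (full sort) the max
  # pre-normalization value is that quantile; post-normalization the max is 1
  q <- oracle_sorted_quantile(vals, 1 - 0.0005)
  v <- img$voxels; v[v > q] <- q
  expected <- (v - min(v)) / (max(v) - min(v))
  expect_equal(clipped$voxels, expected, tolerance = 1e-12)
  expect_equal(range(clipped$voxels), c(0, 1))
})

test_that("clip_and_normalize degenerate and error cases", {
  const <- volumetric_image(array(7, c(6, 6, 6)))
  expect_equal(unique(as.vector(clip_and_normalize(const)$voxels)), 0)
  # exact output range for any non-constant input
  set.seed(9)
  for (rep in 1:5) {
    img <- volumetric_image(array(stats::rnorm(8^3, sd = runif(1, 0.1, 10)),
                                  c(8, 8, 8)))
    rng <- sort(stats::rnorm(2))
    out <- clip_and_normalize(img, 0.0005, rng)
    expect_equal(range(out$voxels), rng)
  }
  bad <- volumetric_image(array(c(NaN, rep(1, 215)), c(6, 6, 6)))
  expect_error(clip_and_normalize(bad), "finite")
  bad2 <- volumetric_image(array(c(Inf, rep(1, 215)), c(6, 6, 6)))
  expect_error(clip_and_normalize(bad2), "finite")
})

test_that("skull stripping zeroes exactly the voxels outside the mask", {
  set.seed(3)
  img <- volumetric_image(array(stats::runif(16^3), c(16, 16, 16)))
  ones <- mask_on(array(1, c(16, 16, 16)), img, "brain")
  expect_equal(apply_brain_mask(img, ones)$voxels, img$voxels)
  zeros <- mask_on(array(0, c(16, 16, 16)), img, "brain")
  expect_true(all(apply_brain_mask(img, zeros)$voxels == 0))
  half <- array(0L, c(16, 16, 16)); half[1:8, , ] <- 1L
  hm <- mask_on(half, img, "brain")
  out <- apply_brain_mask(img, hm)
  expect_equal(out$voxels[1:8, , ], img$voxels[1:8, , ])
  expect_true(all(out$voxels[9:16, , ] == 0))

  other <- mask_on(array(1, c(8, 8, 8)), grid_image(c(8, 8, 8)), "brain")
  expect_error(apply_brain_mask(img, other), "geometry")
})

test_that("mask volume arithmetic and axis-permutation invariance", {
  g1 <- grid_image(c(10, 10, 10))
  expect_equal(mask_volume_ml(mask_on(array(0, c(10, 10, 10)), g1)), 0)
  expect_equal(mask_volume_ml(mask_on(array(1, c(10, 10, 10)), g1)), 1)

  g075 <- grid_image(c(20, 20, 20), spacing = c(0.75, 0.75, 0.75))
  arr <- array(0L, c(20, 20, 20)); arr[seq_len(3163)] <- 1L
  expect_equal(mask_volume_ml(mask_on(arr, g075)), 3163 * 0.421875 / 1000)

  # axis permutation of the grid leaves the volume unchanged
  arr2 <- array(stats::rbinom(4 * 5 * 6, 1, 0.3), c(4, 5, 6))
  v1 <- mask_volume_ml(mask_on(arr2, grid_image(c(4, 5, 6), c(1, 2, 3))))
  v2 <- mask_volume_ml(mask_on(aperm(arr2, c(3, 1, 2)),
                               grid_image(c(6, 4, 5), c(3, 1, 2))))
  expect_equal(v1, v2)
})

test_that("NIfTI write/read round-trips voxels and geometry", {
  set.seed(4)
  img <- volumetric_image(array(stats::rnorm(12 * 10 * 8), c(12, 10, 8)),
                          spacing = c(0.75, 1, 1.25), origin = c(-3, 2, 7))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(img, f)
  back <- read_volume(f)
  expect_equal(back$voxels, img$voxels, tolerance = 1e-6)
  expect_equal(back$spacing, img$spacing, tolerance = 1e-5)
  expect_equal(back$origin, img$origin, tolerance = 1e-4)
  m <- mask_on(array(stats::rbinom(12 * 10 * 8, 1, 0.2), c(12, 10, 8)), img)
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  expect_identical(read_mask(fm, "tumor")$labels, m$labels)
})

test_that("MetaImage and NRRD import agree with the written payload", {
  set.seed(6)
  dims <- c(7L, 6L, 5L)
  vals <- round(stats::runif(prod(dims), 0, 100), 3)
  # hand-construct an .mha (LOCAL payload) the way an external tool would
  f_mha <- tempfile(fileext = ".mha")
  hdr <- paste0("ObjectType = Image\nNDims = 3\nDimSize = 7 6 5\n",
                "ElementSpacing = 0.5 1 2\nOffset = 1 2 3\n",
                "ElementType = MET_FLOAT\nElementDataFile = LOCAL\n")
  con <- file(f_mha, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  img <- read_volume(f_mha)
  expect_identical(image_shape(img), dims)
  expect_equal(img$spacing, c(0.5, 1, 2))
  expect_equal(img$origin, c(1, 2, 3))
  expect_equal(as.vector(img$voxels), vals, tolerance = 1e-4)

  # and a gzip-encoded NRRD with anisotropic space directions
  f_nrrd <- tempfile(fileext = ".nrrd")
  hdr <- paste0("NRRD0004\ntype: double\ndimension: 3\nsizes: 7 6 5\n",
                "encoding: gzip\nendian: little\n",
                "space directions: (0.5,0,0) (0,1,0) (0,0,2)\n",
                "space origin: (1,2,3)\n\n")
  con <- file(f_nrrd, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(memCompress(writeBin(as.numeric(vals), raw(), size = 8), "gzip"),
           con)
  close(con)
  img2 <- read_volume(f_nrrd)
  expect_identical(image_shape(img2), dims)
  expect_equal(img2$spacing, c(0.5, 1, 2))
  expect_equal(as.vector(img2$voxels), vals)
})

test_that("container invariants are enforced", {
  expect_error(volumetric_image(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(volumetric_image(array(0, c(4, 4, 4)), c(1, -1, 1)), "positive")
  skewed <- diag(3); skewed[1, 2] <- 0.1
  expect_error(volumetric_image(array(0, c(4, 4, 4)), orientation = skewed),
               "orthonormal")
  g <- grid_image(c(4, 4, 4))
  expect_error(label_mask(array(2L, c(4, 4, 4)), g, "tumor"), "binary")
  expect_error(label_mask(array(-1L, c(4, 4, 4)), g, "parcellation"),
               "non-negative")
  expect_error(label_mask(array(0L, c(5, 4, 4)), g, "tumor"), "shape")
})
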