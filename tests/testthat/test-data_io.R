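test_that("NIfTI round trip preserves float32 data and spacing", {
  set.seed(1)
  # values exactly representable in float32
  arr <- array(as.numeric(sample(-1000:1000, 4^3, replace = TRUE)) / 16,
               c(4, 4, 4))
  g <- VolumeGrid(arr, spacing = c(0.9, 1.1, 1.25))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(g, f)
  g2 <- readVolume(f)
  expect_identical(volData(g2), arr)
  expect_equal(voxelSpacing(g2), c(0.9, 1.1, 1.25), tolerance = 1e-6)

  f0 <- tempfile(fileext = ".nii.gz")
  writeVolume(VolumeGrid(array(0, c(4, 4, 4))), f0)
  z <- readVolume(f0)
  expect_equal(sum(volData(z)), 0)
  expect_equal(dim(volData(z)), c(4L, 4L, 4L))

  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
})

test_that("subject validation resolves complete directories and names missing roles", {
  cfg <- tinyPhantomConfig(seed = 3L)
  root <- file.path(tempdir(), "cohort_val")
  unlink(root, recursive = TRUE)
  recs <- generateCohort(2, cfg, root)
  expect_length(recs, 2)
  expect_s3_class(validateSubject(file.path(root, "sub-001")), "SubjectRecord")

  unlink(file.path(root, "sub-002", "T2_mask.nii.gz"))
  expect_error(validateSubject(file.path(root, "sub-002")), "T2_mask")
  res <- suppressWarnings(validateCohort(root))
  expect_length(res$records, 1)
  expect_named(res$failures, "sub-002")
})

test_that("resampling is identity on matching grids and keeps masks binary", {
  set.seed(2)
  g <- VolumeGrid(array(rnorm(5 * 6 * 7), c(5, 6, 7)))
  same <- resampleLike(g, g, "linear")
  expect_equal(volData(same), volData(g), tolerance = 1e-12)

  m <- BinaryMask(array(rbinom(5 * 6 * 7, 1, 0.3), c(5, 6, 7)))
  ref <- VolumeGrid(array(0, c(9, 11, 13)))
  mr <- resampleLike(m, ref, "nearest")
  expect_true(all(volData(mr) %in% c(0, 1)))
  expect_s4_class(mr, "BinaryMask")
  expect_error(resampleLike(g, ref, "cubic"))
})

test_that("linear upsampling of a ramp interpolates midpoints exactly", {
  # ramp 0..1 over 5 points upsampled to 9: corner-aligned outputs follow
  # seq(0, 1, length.out = 9), so aligned coordinates keep exact midpoints
  ramp <- array(rep(seq(0, 1, length.out = 5), times = 9), c(5, 3, 3))
  out <- resampleLike(VolumeGrid(ramp), VolumeGrid(array(0, c(9, 3, 3))),
                      "linear")
  expect_equal(volData(out)[, 2, 2], seq(0, 1, length.out = 9),
               tolerance = 1e-12)
})

test_that("z-score normalisation follows the non-zero-voxel convention", {
  arr <- array(0, c(2, 2, 2))
  arr[1:3] <- c(2, 4, 6)
  out <- volData(zscoreNormalize(VolumeGrid(arr), eps = 1e-12))
  sigma <- sqrt(mean((c(2, 4, 6) - 4)^2)) # population sd = 1.63299
  expect_equal(out[1:3], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(out[1:3], (c(2, 4, 6) - 4) / sigma, tolerance = 1e-9)
  # zero background passes through the same affine map by default
  expect_equal(out[4], (0 - 4) / sigma, tolerance = 1e-9)
  out0 <- volData(zscoreNormalize(VolumeGrid(arr), preserve_zero_background = TRUE))
  expect_equal(out0[4], 0)

  cst <- array(0, c(3, 3, 3)); cst[1:5] <- 7
  outc <- volData(zscoreNormalize(VolumeGrid(cst)))
  expect_equal(outc[1:5], rep(0, 5))

  expect_warning(zscoreNormalize(VolumeGrid(array(0, c(2, 2, 2)))), "all-zero")
})

test_that("z-score output moments and affine invariance hold on a phantom", {
  s <- generateSubject(tinyPhantomConfig(seed = 11L))
  fl <- array(mmChannels(s$volume)[3, , , ], dim(volData(s$mask)))
  g <- VolumeGrid(fl)
  out <- volData(zscoreNormalize(g))
  nz <- fl != 0
  expect_lt(abs(mean(out[nz])), 1e-6)
  expect_equal(sqrt(mean((out[nz] - mean(out[nz]))^2)), 1, tolerance = 1e-3)
  # positive rescaling of the input leaves the normalised output unchanged
  out2 <- volData(zscoreNormalize(VolumeGrid(fl * 3.7)))
  expect_equal(out2, out, tolerance = 1e-6)
})

test_that("binarization is a strict greater-than comparison and idempotent", {
  g <- VolumeGrid(array(c(0.4, 0.5, 0.6, 0, 1, 0.2, 0.7, 1), c(2, 2, 2)))
  b <- binarize(g)
  expect_equal(volData(b)[1:3], c(0, 0, 1))
  expect_equal(volData(binarize(VolumeGrid(array(0, c(2, 2, 2))))),
               array(0, c(2, 2, 2)))
  expect_equal(volData(binarize(VolumeGrid(volData(b)))), volData(b))
})

test_that("cohort split has exact sizes, determinism and no patient leakage", {
  ids <- sprintf("P%02d", 1:60)
  sp <- splitCohort(ids, seed = 7)
  expect_length(sp$train_ids, 42)
  expect_length(sp$val_ids, 9)
  expect_length(sp$test_ids, 9)
  expect_identical(splitCohort(ids, seed = 7), sp)
  expect_false(identical(splitCohort(ids, seed = 8), sp))
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_length(intersect(sp$val_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)
  expect_error(splitCohort(c("a", "b"), seed = 1), "at least 3")
  expect_error(splitCohort(c("a", "a", "b", "c")), "unique")

  f <- tempfile(fileext = ".tsv")
  writeSplitManifest(sp, f)
  df <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(table(df$split)[["train"]], 42)
  expect_equal(readLines(f, n = 1), "# seed=7")
})

test_that("lesion ratio pools voxels and is additive across cohorts", {
  m1 <- BinaryMask(array(c(rep(1, 4), rep(0, 4)), c(2, 2, 2)))
  expect_equal(lesionRatio(list(m1))$lesion_ratio_percent, 50)
  m0 <- BinaryMask(array(0, c(2, 2, 2)))
  expect_equal(lesionRatio(list(m0, m0))$lesion_ratio_percent, 0)
  set.seed(3)
  m2 <- BinaryMask(array(rbinom(27, 1, 0.2), c(3, 3, 3)))
  r12 <- lesionRatio(list(m1, m2))
  r1 <- lesionRatio(list(m1)); r2 <- lesionRatio(list(m2))
  expect_equal(r12$lesion_ratio_percent,
               (r1$lesion_ratio_percent * r1$total_voxels +
                r2$lesion_ratio_percent * r2$total_voxels) /
                 (r1$total_voxels + r2$total_voxels))
  expect_error(lesionRatio(list()), "empty")
})
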