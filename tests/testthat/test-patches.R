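test_that("centre sampling honours the lesion branch, clamping and fallback", {
  m <- array(0, c(40, 40, 40))
  m[5, 6, 7] <- 1 # single lesion voxel, near a boundary
  mask <- BinaryMask(m)
  ctr <- withr::with_seed(1, sampleCenter(mask, TRUE, 16L))
  expect_identical(attr(ctr, "drawn"), c(4L, 5L, 6L)) # 0-based pre-clamp
  expect_true(all(ctr >= 8L) && all(ctr <= 32L))      # clamped to fit

  expect_warning(
    ctr0 <- withr::with_seed(2, sampleCenter(BinaryMask(array(0, c(20, 20, 20))),
                                             TRUE, 16L)),
    "all-zero")
  expect_true(all(ctr0 >= 0L) && all(ctr0 < 20L))

  # non-lesion branch never lands on the lesion voxel pre-clamp
  for (k in 1:20) {
    c2 <- withr::with_seed(k, sampleCenter(mask, FALSE, 8L))
    expect_false(identical(attr(c2, "drawn"), c(4L, 5L, 6L)))
  }
})

test_that("patch extraction clamps to identity and pads small volumes", {
  cfg <- tinyPhantomConfig(seed = 41L)
  s <- generateSubject(cfg)
  p <- extractPatch(s$volume, s$mask, c(16L, 16L, 16L), 32L)
  expect_identical(p$image, mmChannels(s$volume))
  expect_identical(p$mask, volData(s$mask))

  les <- which(volData(s$mask) == 1, arr.ind = TRUE)[1, ] - 1L
  pl <- extractPatch(s$volume, s$mask, as.integer(les), 16L)
  expect_gte(sum(pl$mask), 1)

  cst <- MultiModalVolume(array(5, c(3, 8, 8, 8)))
  pm <- extractPatch(cst, BinaryMask(array(0, c(8, 8, 8))), c(4L, 4L, 4L), 16L)
  expect_equal(dim(pm$image), c(3L, 16L, 16L, 16L))
  expect_setequal(unique(as.numeric(pm$image)), c(0, 5)) # zero padding
})

test_that("balanced streams respect p_lesion extremes and are reproducible", {
  s <- normalizeSubject(generateSubject(tinyPhantomConfig(seed = 42L)))
  st1 <- balancedPatchStream(s, samplerConfig(16L, p_lesion = 1, seed = 5L))
  for (k in 1:10) expect_gte(sum(st1()$mask), 1)

  st0 <- balancedPatchStream(s, samplerConfig(16L, p_lesion = 0, seed = 5L))
  hits <- vapply(1:200, function(k) {
    p <- st0()
    c3 <- 8L # patch centre voxel (0-based origin + size/2)
    p$mask[c3 + 1, c3 + 1, c3 + 1]
  }, numeric(1))
  prev <- mean(volData(s$mask))
  expect_lte(mean(hits), prev + 3 * sqrt(prev * (1 - prev) / 200))

  a <- balancedPatchStream(s, samplerConfig(16L, seed = 9L))
  b <- balancedPatchStream(s, samplerConfig(16L, seed = 9L))
  for (k in 1:5) expect_identical(a(), b())
})

test_that("sampler balance matches p_lesion within binomial tolerance", {
  s <- generateSubject(tinyPhantomConfig(seed = 43L))
  for (p in c(0.25, 0.75)) {
    st <- balancedPatchStream(s, samplerConfig(16L, p_lesion = p, seed = 17L))
    frac <- mean(vapply(1:400, function(k) st()$lesion_centered, logical(1)))
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 400))
  }
})

test_that("the augmentation chain has exact identity, involution and permutation laws", {
  p <- makeLesionPatch()
  off <- augmentConfig(flip_prob = 0, scale_range = 0, rot_range = 0,
                       translate_range = 0, noise_sd = 0, bias_amplitude = 0)
  expect_identical(applyAugmentations(p, off), p)

  flips <- augmentConfig(flip_prob = 1, scale_range = 0, rot_range = 0,
                         translate_range = 0, noise_sd = 0, bias_amplitude = 0)
  once <- applyAugmentations(p, flips)
  twice <- applyAugmentations(once, flips)
  expect_identical(twice$image, p$image) # flips are involutions
  expect_identical(twice$mask, p$mask)
  # flip-only: mask voxel multiset and lesion count exactly preserved
  expect_identical(sort(as.numeric(once$mask)), sort(as.numeric(p$mask)))
  expect_identical(sum(once$mask), sum(p$mask))

  disabled <- augmentConfig(enabled = FALSE)
  expect_identical(applyAugmentations(p, disabled), p)
})

test_that("image-only degradations leave the mask bit-identical and binary", {
  p <- makeLesionPatch()
  noisy <- augmentConfig(flip_prob = 0, scale_range = 0, rot_range = 0,
                         translate_range = 0, noise_sd = 0.05,
                         bias_amplitude = 0.2)
  out <- withr::with_seed(3, applyAugmentations(p, noisy))
  expect_identical(out$mask, p$mask)
  expect_false(identical(out$image, p$image))

  full <- augmentConfig()
  for (k in 1:10) {
    out <- withr::with_seed(k, applyAugmentations(p, full))
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("affine resampling changes ellipsoid lesion volume by a bounded amount", {
  # ellipsoid fixture with an analytic mask; default affine ranges
  s <- 32L
  msk <- array(0, c(s, s, s))
  ax <- (seq_len(s) - 16.5)
  r2 <- outer(outer((ax / 6)^2, (ax / 4)^2, `+`), (ax / 5)^2, `+`)
  msk[r2 <= 1] <- 1
  p <- structure(list(image = array(0, c(3, s, s, s)), mask = msk,
                      origin = c(0L, 0L, 0L), lesion_centered = TRUE),
                 class = "Patch")
  affine <- augmentConfig(flip_prob = 0, noise_sd = 0, bias_amplitude = 0)
  n0 <- sum(msk)
  for (k in 1:10) {
    out <- withr::with_seed(100 + k, applyAugmentations(p, affine))
    expect_lte(abs(sum(out$mask) - n0) / n0, 0.30)
  }
})
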