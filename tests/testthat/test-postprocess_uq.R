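test_that("blob suppression filters by component size with exact semantics", {
  # constructed 10^3 grid with components of sizes 2, 5 and 9
  m <- array(0, c(10, 10, 10))
  m[1:2, 1, 1] <- 1                   # size 2
  m[5, 5, 5] <- 1; m[5:8, 6, 5] <- 1  # size 5 (26-connected L-shape)
  m[1:9, 10, 10] <- 1                 # size 9
  out <- removeSmallBlobs(m, min_voxels = 5, connectivity = 26)
  expect_equal(sum(out), 14)
  expect_true(all(out <= m))
  expect_equal(removeSmallBlobs(m, 0), m)         # identity at threshold 0
  expect_equal(removeSmallBlobs(m, 3)[1:2, 1, 1], c(0, 0))
  # idempotence and monotonicity in min_voxels
  expect_equal(removeSmallBlobs(out, 5), out)
  bigger <- removeSmallBlobs(m, 6)
  expect_true(all(bigger <= out))
  expect_error(removeSmallBlobs(m, -1), "non-negative")
  expect_error(removeSmallBlobs(m, 5, connectivity = 18), "connectivity")

  bm <- BinaryMask(m)
  out_s4 <- removeSmallBlobs(bm, 5)
  expect_s4_class(out_s4, "BinaryMask")
  expect_equal(volData(out_s4), out)
})

test_that("component labelling agrees with a flood-fill oracle on random masks", {
  set.seed(10)
  for (k in 1:100) {
    m <- array(rbinom(12^3, 1, runif(1, 0.05, 0.4)), c(12, 12, 12))
    for (conn in c(6L, 26L)) {
      thr <- sample(1:6, 1)
      expect_identical(removeSmallBlobs(m, thr, conn),
                       oracleRemoveSmall(m, thr, conn))
    }
  }
})

test_that("binary entropy has the analytic extremes and interior value", {
  expect_equal(binaryEntropy(0.5), log(2), tolerance = 1e-12)
  expect_equal(binaryEntropy(c(0, 1)), c(0, 0))
  expect_equal(binaryEntropy(0.25), 0.562335, tolerance = 1e-6)
  expect_error(binaryEntropy(1.2), "0, 1")
})

test_that("MC dropout degenerates cleanly and bounds its mean", {
  s <- normalizeSubject(generateSubject(tinyPhantomConfig(seed = 81L)))
  net0 <- buildNetwork(tinyNetSpec(0), seed = 3) # dropout layers at rate 0
  um0 <- mcDropoutPredict(net0, s$volume, n_passes = 3L, patch_size = 32L)
  single <- volData(slidingWindowPredict(net0, s$volume, 32L))
  expect_equal(meanProb(um0), single, tolerance = 1e-12)
  expect_equal(uncertaintyField(um0), binaryEntropy(single), tolerance = 1e-12)

  net <- buildNetwork(tinyNetSpec(0.25), seed = 3)
  um <- mcDropoutPredict(net, s$volume, n_passes = 4L, patch_size = 32L)
  mp <- meanProb(um)
  # entropy peaks exactly where the mean probability is nearest one half
  expect_true(max(uncertaintyField(um)) <=
                binaryEntropy(mp[which.min(abs(mp - 0.5))]) + 1e-12)
  expect_true(all(mp >= 0 & mp <= 1))
  # reproducible given the seed
  um2 <- mcDropoutPredict(net, s$volume, n_passes = 4L, patch_size = 32L)
  expect_identical(meanProb(um2), mp)

  nodrop <- buildNetwork(tinyNetSpec(0), seed = 3)
  for (l in msseg3d:::netLayers(nodrop))
    if (identical(l$type, "dropout3d")) l$type <- "relu"
  expect_error(mcDropoutPredict(nodrop, s$volume, 3L, 32L), "dropout")
})

test_that("ensemble uncertainty is the population variance of member fields", {
  s <- normalizeSubject(generateSubject(tinyPhantomConfig(seed = 82L)))
  net <- buildNetwork(tinyNetSpec(), seed = 5)
  ck <- list(spec = tinyNetSpec(), state = stateDict(net))
  um <- ensemblePredict(list(ck, ck, ck), s$volume, patch_size = 32L)
  expect_equal(max(uncertaintyField(um)), 0)
  expect_lte(max(uncertaintyField(um)), 0.25)

  # two constant members at probabilities ~0 and ~1: mean 1/2, variance 1/4
  mk_const <- function(logit) {
    n <- buildNetwork(tinyNetSpec(), seed = 1)
    for (l in msseg3d:::netLayers(n)) {
      for (nm in l$param_names) l[[nm]] <- l[[nm]] * 0
      if (identical(l$type, "bn")) l$gamma[] <- 0
    }
    layers <- msseg3d:::netLayers(n)
    layers[[length(layers) - 1]]$b[] <- logit
    n
  }
  um2 <- ensemblePredict(list(mk_const(-30), mk_const(30)), s$volume, 32L)
  expect_equal(mean(meanProb(um2)), 0.5, tolerance = 1e-9)
  expect_equal(mean(uncertaintyField(um2)), 0.25, tolerance = 1e-9)

  bad <- list(ck, list(spec = reducedNetSpec(), state = ck$state))
  expect_error(ensemblePredict(bad, s$volume, 32L), "mismatched")
})

test_that("expected calibration error matches hand cases and flags associations", {
  # perfectly confident, perfectly correct
  r0 <- expectedCalibrationError(c(rep(1, 5), rep(0, 5)),
                                 c(rep(1, 5), rep(0, 5)))
  expect_equal(r0$ece, 0)
  # single-bin hand case: all confidence 0.9, all correct
  r1 <- expectedCalibrationError(rep(0.9, 100), rep(1, 100))
  expect_equal(r1$ece, 0.1, tolerance = 1e-12)
  expect_equal(sum(r1$bins$count), 100)
  expect_error(expectedCalibrationError(numeric(0), numeric(0)), "empty")
  expect_error(expectedCalibrationError(c(0.5, 2), c(0, 1)))

  # calibrated by construction: P(label = 1 | p) = p
  set.seed(12)
  p <- runif(1e5)
  y <- rbinom(1e5, 1, p)
  rc <- expectedCalibrationError(p, y)
  expect_lte(rc$ece, 0.02)

  # uncertainty-error association is positive when errors sit near p = 0.5
  r2 <- expectedCalibrationError(p, y)
  expect_gt(r2$unc_error_correlation, 0)
})
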