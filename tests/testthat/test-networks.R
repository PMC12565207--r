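test_that("MBConv blocks downsample by stride and carry residuals when shapes allow", {
  spec2 <- mbconvSpec(4L, 6L, stride = 2L)
  expect_false(spec2$use_residual)
  blk <- withr::with_seed(1, buildMBConv3d(spec2))
  x <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  y <- msseg3d:::mbconvForward(blk, x)
  expect_equal(dim(y), c(6L, 8L, 8L, 8L))

  spec1 <- mbconvSpec(5L, 5L, stride = 1L)
  expect_true(spec1$use_residual)
  blk1 <- withr::with_seed(2, buildMBConv3d(spec1))
  # zero the projection: the block reduces to the residual identity
  proj <- blk1$layers[[4]]
  proj$w[] <- 0
  bn <- blk1$layers[[5]]
  bn$gamma[] <- 1; bn$beta[] <- 0
  x1 <- array(rnorm(5 * 8^3), c(5, 8, 8, 8))
  y1 <- msseg3d:::mbconvForward(blk1, x1)
  expect_equal(y1, x1, tolerance = 1e-12)

  expect_error(mbconvSpec(4L, 4L, stride = 3L))
})

test_that("parameter counts match hand counts for blocks and convolutions", {
  # expansion 1, in 32 -> out 48, BN affine, no conv biases:
  # depthwise 32*27 + BN 64 + projection 32*48 + BN 96 = 2560
  blk <- withr::with_seed(3, buildMBConv3d(mbconvSpec(32L, 48L, stride = 1L)))
  expect_equal(countTrainableParameters(blk), 864 + 64 + 1536 + 96)
  expect_equal(countTrainableParameters(blk), 2560)

  lone <- withr::with_seed(4, msseg3d:::newConv3d(1L, 1L, k = 1L, pad = 0L,
                                                  bias = TRUE))
  expect_equal(countTrainableParameters(lone), 2)
  stem <- withr::with_seed(5, msseg3d:::newConv3d(3L, 32L, k = 3L, bias = TRUE))
  expect_equal(countTrainableParameters(stem), 3 * 32 * 27 + 32)
  expect_equal(countTrainableParameters(stem), 2624)
})

test_that("the proposed network is at least tenfold smaller than the baseline", {
  eff <- buildNetwork(networkSpec("efficientnet3d_unet"), seed = 1)
  base <- buildNetwork(networkSpec("unet3d_baseline"), seed = 1)
  n_eff <- countTrainableParameters(eff)
  n_base <- countTrainableParameters(base)
  expect_lte(n_eff, 710000)
  expect_lt(n_eff, n_base / 10)
})

test_that("forward passes have the shape/probability contract and reject bad sizes", {
  net <- buildNetwork(tinyNetSpec(), seed = 6)
  x <- array(rnorm(3 * 32^3), c(3, 32, 32, 32))
  y <- netForward(net, x)
  expect_equal(dim(y), c(1L, 32L, 32L, 32L))
  expect_true(all(y > 0 & y < 1))
  y0 <- netForward(net, array(0, c(3, 16, 16, 16)))
  expect_true(all(is.finite(y0)))
  expect_error(netForward(net, array(0, c(3, 24, 24, 24))), "divisible by 16")
  expect_error(netForward(net, array(0, c(2, 32, 32, 32))))

  p1 <- predictPatch(net, x)
  p2 <- predictPatch(net, x)
  expect_identical(p1, p2) # eval-mode determinism
  expect_gt(mean(p1), 0.05)
  expect_lt(mean(p1), 0.95)

  base <- buildNetwork(networkSpec("unet3d_baseline", stem_channels = 4L,
                                   encoder_channels = c(6L, 8L, 10L, 12L),
                                   bottleneck_channels = 12L,
                                   decoder_channels = c(10L, 8L, 6L, 4L)),
                       seed = 7)
  yb <- netForward(base, array(rnorm(3 * 16^3), c(3, 16, 16, 16)))
  expect_equal(dim(yb), c(1L, 16L, 16L, 16L))
  expect_true(all(yb > 0 & yb < 1))
})

test_that("forward passes stay NaN-free across many random inits and inputs", {
  for (k in 1:30) {
    net <- buildNetwork(tinyNetSpec(), seed = k)
    x <- withr::with_seed(1000 + k, array(rnorm(3 * 16^3), c(3, 16, 16, 16)))
    expect_true(all(is.finite(netForward(net, x))))
  }
})

test_that("residual MBConv blocks pass finite non-zero gradients", {
  blk <- withr::with_seed(8, buildMBConv3d(mbconvSpec(4L, 4L)))
  x <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  y <- msseg3d:::mbconvForward(blk, x, training = TRUE)
  gx <- msseg3d:::mbconvBackward(blk, array(1, dim(y)))
  expect_true(all(is.finite(gx)))
  expect_gt(max(abs(gx)), 0)
  dw <- blk$layers[[1]]
  expect_true(all(is.finite(dw$gw)))
  expect_gt(max(abs(dw$gw)), 0)
})

test_that("sliding-window prediction tiles, averages and matches single windows", {
  net <- buildNetwork(tinyNetSpec(), seed = 9)
  s <- normalizeSubject(generateSubject(tinyPhantomConfig(seed = 51L)))
  one <- slidingWindowPredict(net, s$volume, patch_size = 32L)
  direct <- predictPatch(net, mmChannels(s$volume))
  expect_equal(volData(one), direct, tolerance = 1e-12)

  # overlapping tiling on a larger volume: weights sum to one everywhere
  big <- MultiModalVolume(array(rnorm(3 * 24^3), c(3, 24, 24, 24)))
  res <- slidingWindowPredict(net, big, patch_size = 16L, overlap = 0.5,
                              return_weights = TRUE)
  expect_true(all(abs(res$weights - 1) < 1e-12))
  expect_true(all(volData(res$probs) > 0 & volData(res$probs) < 1))

  # constant-output network (all-zero weights, biased head) stays constant
  cnet <- buildNetwork(tinyNetSpec(), seed = 10)
  for (l in msseg3d:::netLayers(cnet)) {
    for (nm in l$param_names) l[[nm]] <- l[[nm]] * 0
    if (identical(l$type, "bn")) l$gamma[] <- 0
  }
  head_conv <- msseg3d:::netLayers(cnet)[[length(msseg3d:::netLayers(cnet)) - 1]]
  head_conv$b[] <- 2
  cp <- slidingWindowPredict(cnet, big, patch_size = 16L, overlap = 0.5)
  expect_equal(max(abs(volData(cp) - 1 / (1 + exp(-2)))), 0, tolerance = 1e-12)
})
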