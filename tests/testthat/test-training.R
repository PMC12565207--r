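test_that("cosine annealing hits its anchor points and restarts cycles", {
  expect_equal(cosineAnnealingLR(0, 5e-4, 80), 5e-4)
  expect_equal(cosineAnnealingLR(80, 5e-4, 80), 5e-4) # cycle restart
  expect_equal(cosineAnnealingLR(40, 5e-4, 80), 2.5e-4, tolerance = 1e-12)
  expect_equal(cosineAnnealingLR(10, 1e-3, 10, lr_min = 1e-5), 1e-3)
  lr79 <- cosineAnnealingLR(79, 5e-4, 80)
  expect_lt(lr79, 1e-6 + 5e-4 * (1 + cos(pi * 79 / 80)) / 2 + 1e-12)
  expect_error(cosineAnnealingLR(5, 1e-3, 0), "t_max")
})

test_that("config presets carry the protocol defaults and the alternative reading", {
  t3 <- trainConfig("efficientnet3d_unet")
  expect_equal(t3$lr0, 5e-4)
  expect_equal(t3$t_max, 80L)
  expect_equal(t3$batch_size, 4L)
  expect_equal(t3$max_epochs, 120L)
  expect_equal(t3$patience, 25L)
  expect_equal(t3$alpha, 0.7)
  expect_equal(trainConfig("unet3d_baseline")$lr0, 1e-4)
  alt <- trainConfig("efficientnet3d_unet", preset = "text_343")
  expect_equal(alt$lr0, 1e-4)
  expect_equal(alt$t_max, 10L)
  expect_equal(trainConfig("unet3d_baseline", preset = "text_343")$lr0, 3e-5)
})

test_that("early stopping follows the patience rule and keeps the best epoch", {
  p <- makeLesionPatch()
  net <- buildNetwork(tinyNetSpec(0), seed = 1)
  trace <- c(0.2, 0.3, 0.3, 0.3, 0.3, 0.3)
  evaluator <- function(net, epoch) trace[epoch]
  cfg <- trainConfig("efficientnet3d_unet", batch_size = 1L, max_epochs = 6L,
                     patience = 2L, patches_per_epoch = 1L, seed = 1L)
  fit <- trainModel(net, function() p, list(), cfg, val_evaluator = evaluator)
  h <- fit$history
  expect_equal(nrow(h), 4) # stops at epoch 4
  expect_true(attr(h, "stopped_early"))
  expect_equal(attr(h, "best_epoch"), 2)
  expect_equal(fit$checkpoint$best_val_dice, max(h$val_dice))
  # recorded lr trace equals the schedule exactly
  expect_equal(h$lr, vapply(h$epoch - 1, cosineAnnealingLR, numeric(1),
                            lr0 = cfg$lr0, t_max = cfg$t_max))
})

test_that("training is bit-reproducible given one seed", {
  p <- makeLesionPatch()
  cfg <- trainConfig("efficientnet3d_unet", batch_size = 2L, max_epochs = 2L,
                     patience = 5L, patches_per_epoch = 4L, seed = 3L)
  run <- function() {
    net <- buildNetwork(tinyNetSpec(), seed = 11)
    s <- normalizeSubject(generateSubject(tinyPhantomConfig(seed = 61L)))
    st <- balancedPatchStream(s, samplerConfig(16L, seed = 7L))
    trainModel(net, st, list(), cfg, val_evaluator = function(n, e) {
      mean(predictPatch(n, p$image))
    })
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$checkpoint$state, f2$checkpoint$state)
})

test_that("a non-finite loss aborts with a diagnostic", {
  net <- buildNetwork(tinyNetSpec(0), seed = 2)
  bad <- makeLesionPatch()
  bad$image[1] <- Inf
  cfg <- trainConfig("efficientnet3d_unet", batch_size = 1L, max_epochs = 1L,
                     patches_per_epoch = 1L, seed = 1L)
  expect_error(trainModel(net, function() bad, list(), cfg,
                          val_evaluator = function(n, e) 0),
               "non-finite")
})

test_that("ensembles require distinct seeds and produce differing members", {
  s <- normalizeSubject(generateSubject(tinyPhantomConfig(seed = 71L)))
  cfg <- trainConfig("efficientnet3d_unet", batch_size = 2L, max_epochs = 1L,
                     patience = 5L, patches_per_epoch = 4L, seed = 1L)
  mk <- function(seed) balancedPatchStream(s, samplerConfig(16L, seed = seed))
  cks <- trainEnsemble(2L, tinyNetSpec(), mk, list(s), cfg, seeds = c(5L, 6L))
  expect_length(cks, 2)
  expect_false(identical(cks[[1]]$state, cks[[2]]$state))
  um <- ensemblePredict(cks, s$volume, patch_size = 32L)
  expect_gt(mean(uncertaintyField(um)), 0)
  expect_error(trainEnsemble(2L, tinyNetSpec(), mk, list(s), cfg,
                             seeds = c(5L, 5L)), "distinct")
})

test_that("state dictionaries round-trip through fresh networks", {
  net <- buildNetwork(tinyNetSpec(), seed = 13)
  st <- stateDict(net)
  net2 <- buildNetwork(tinyNetSpec(), seed = 99)
  loadStateDict(net2, st)
  x <- array(rnorm(3 * 16^3), c(3, 16, 16, 16))
  expect_identical(predictPatch(net, x), predictPatch(net2, x))
})
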