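test_that("dataset splitting is a seeded disjoint exhaustive partition", {
  ids <- sprintf("img_%02d", 1:10)
  sp <- splitDataset(ids, 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, splitDataset(ids, 0.8, seed = 3))
  expect_false(identical(sp$train, splitDataset(ids, 0.8, seed = 4)$train))
  expect_error(splitDataset("one"), "at least 2")
  # neither side may be empty even under extreme fractions
  sp2 <- splitDataset(ids[1:2], 0.99, seed = 1)
  expect_length(sp2$train, 1)
  expect_length(sp2$test, 1)
})

test_that("flip augmentation maps pixels and dots together", {
  cfg <- smallSceneConfig(countRange = c(4, 7))
  sc <- generateScene(cfg, 2)

  expect_identical(augmentSample(sc, "none"), sc)
  # involution: flipping twice restores the sample
  expect_equal(augmentSample(augmentSample(sc, "hflip"), "hflip"), sc)
  expect_equal(augmentSample(augmentSample(sc, "vflip"), "vflip"), sc)
  # counts are invariant
  expect_equal(dotCount(augmentSample(sc, "hflip")), dotCount(sc))

  # coordinate law: col' = width - 1 - col
  ann <- DotAnnotation(rbind(c(10, 3)), c(32, 64))
  im <- AnnotatedImage(matrix(0.5, 32, 64), ann)
  expect_equal(dotPoints(augmentSample(im, "hflip"))[1, ],
               c(row = 10, col = 60))
  expect_equal(dotPoints(augmentSample(im, "vflip"))[1, ],
               c(row = 21, col = 3))
})

test_that("center patch extraction windows pixels and dots", {
  px <- matrix(runif(256 * 256), 256, 256)
  ann <- DotAnnotation(rbind(c(127.5, 127.5), c(10, 10)), c(256, 256))
  im <- AnnotatedImage(px, ann)

  expect_identical(extractCenterPatch(im, 256), im)

  patch <- extractCenterPatch(im, 128)
  expect_equal(dim(pixelGrid(patch)), c(128, 128))
  expect_equal(dotCount(patch), 1)     # outer-margin dot dropped
  expect_lt(max(abs(dotPoints(patch)[1, ] - c(64, 64))), 0.5 + 1e-9)

  expect_error(extractCenterPatch(patch, 256), "smaller")
})

test_that("patch normalization standardizes and guards constants", {
  p <- matrix(runif(64), 8, 8)
  z <- normalizePatch(p)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)

  expect_identical(normalizePatch(matrix(0.7, 5, 5)), matrix(0, 5, 5))

  q <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(normalizePatch(q), (q - 1.5) / sd(c(0, 1, 2, 3)))
})

test_that("learning-rate schedule follows the step decay", {
  cfg <- TrainConfig(epochs = 30)
  expect_equal(lrAtEpoch(cfg, 0), 0.01)
  expect_equal(lrAtEpoch(cfg, 9), 0.01)
  expect_equal(lrAtEpoch(cfg, 10), 0.001)
  expect_equal(lrAtEpoch(cfg, 25), 0.0001)
  expect_error(lrAtEpoch(cfg, 30), "epoch")
  expect_error(lrAtEpoch(cfg, -1), "epoch")
})

test_that("weight decay shrinks parameters when gradients vanish", {
  eng <- asNamespace("dropcount")
  net <- buildUNet(unetSpec(baseChannels = 2), initSeed = 1)
  zero <- eng$.zeroGrads(net@steps)
  upd <- eng$.sgdStep(net@steps, zero, eng$.zeroVelocity(net@steps),
                      lr = 0.01, momentum = 0.8, weightDecay = 0.005)
  for (i in seq_along(net@steps)) {
    if (is.null(net@steps[[i]]$W)) next
    expect_lt(norm(upd$steps[[i]]$W, "F"), norm(net@steps[[i]]$W, "F"))
  }
})

test_that("training descends, logs faithfully and reproduces exactly", {
  cfg <- smallSceneConfig(countRange = c(3, 6), seed = 40)
  samples <- lapply(1:12, function(i)
    generateScene(cfg, cfg@seed + i, sprintf("s%02d", i)))
  kern <- KernelSpec(sigma = 2)
  tc <- TrainConfig(epochs = 5, batchSize = 4, patchSize = 64, seed = 7)
  net <- buildUNet(unetSpec(baseChannels = 4), initSeed = 7)

  log <- trainNetwork(net, samples, kern, tc)
  expect_length(log@epochLoss, 5)
  expect_length(log@epochLr, 5)
  expect_identical(log@epochLr, lrAtEpoch(tc, 0:4))
  expect_lt(log@epochLoss[5], log@epochLoss[1])

  log2 <- trainNetwork(net, samples, kern, tc)
  expect_identical(log@epochLoss, log2@epochLoss)
  expect_identical(trainedNetwork(log)@steps, trainedNetwork(log2)@steps)
  # the input network is left untouched
  expect_false(identical(net@steps, trainedNetwork(log)@steps))
})

test_that("either family can overfit one repeated sample", {
  cfg <- smallSceneConfig(countRange = c(4, 4), seed = 60,
                          imageHeight = 32, imageWidth = 32)
  sample <- generateScene(cfg, 61)
  kern <- KernelSpec(sigma = 1.5)
  for (spec in list(unetSpec(baseChannels = 4), fcrnSpec(baseChannels = 4))) {
    # constant learning rate: this probes gradient flow, not the schedule
    tc <- TrainConfig(epochs = 200, batchSize = 1, patchSize = 32,
                      augmentFlips = FALSE, lrDecayEvery = 200, seed = 2)
    log <- trainNetwork(buildNetwork(spec, initSeed = 2), list(sample),
                        kern, tc)
    expect_lt(min(log@epochLoss), 0.1 * log@epochLoss[1])
  }
})
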