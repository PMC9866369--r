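# Structural inspection helpers: count convolution layers before the 1x1
# bottleneck (FCRN) and skip connections (U-Net) from the step sequence.
fcrnEncoderConvs <- function(net) {
  ops <- vapply(net@steps, `[[`, "", "op")
  khs <- vapply(net@steps, function(s) if (is.null(s$kh)) NA_real_ else s$kh,
                numeric(1))
  bottleneck <- which(ops == "conv" & khs == 1)[1]
  sum(ops[seq_len(bottleneck - 1)] == "conv")
}
unetSkips <- function(net) {
  sum(vapply(net@steps, `[[`, "", "op") == "concat")
}

test_that("FCRN structure follows the growing-block design", {
  net <- buildFCRN(fcrnSpec(baseChannels = 2), initSeed = 1)
  expect_equal(fcrnEncoderConvs(net), 6)   # 1 + 2 + 3 convs before pool/bottleneck
  net4 <- buildFCRN(fcrnSpec(baseChannels = 2, nBlocks = 4), initSeed = 1)
  expect_equal(fcrnEncoderConvs(net4), 10) # 1 + 2 + 3 + 4
  # first block uses the large kernel, later blocks the small one
  khs <- vapply(net@steps, function(s) if (is.null(s$kh)) NA_real_ else s$kh,
                numeric(1))
  convs <- which(vapply(net@steps, `[[`, "", "op") == "conv")
  expect_equal(khs[convs[1]], 5)
  expect_equal(khs[convs[2]], 3)
  expect_error(buildFCRN(unetSpec()), "family")
})

test_that("U-Net structure has one skip connection per resolution level", {
  net <- buildUNet(unetSpec(baseChannels = 2), initSeed = 1)
  expect_equal(unetSkips(net), 3)
  net2 <- buildUNet(unetSpec(baseChannels = 2, nBlocks = 2), initSeed = 1)
  expect_equal(unetSkips(net2), 2)
  expect_error(buildUNet(fcrnSpec()), "family")
})

test_that("both families preserve 256x256 spatial shape", {
  img <- matrix(runif(256 * 256), 256, 256)
  for (build in list(buildFCRN, buildUNet)) {
    spec <- if (identical(build, buildFCRN)) fcrnSpec(baseChannels = 2)
            else unetSpec(baseChannels = 2)
    out <- predictDensity(build(spec, initSeed = 1), img)
    expect_equal(dim(out), c(256, 256))
  }
})

test_that("builds are deterministic and parameter count is spec-pure", {
  a <- buildUNet(unetSpec(baseChannels = 3), initSeed = 9)
  b <- buildUNet(unetSpec(baseChannels = 3), initSeed = 9)
  expect_identical(a@steps, b@steps)
  expect_identical(parameterCount(a), parameterCount(b))
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predictDensity(a, img), predictDensity(b, img))
  c <- buildUNet(unetSpec(baseChannels = 3), initSeed = 10)
  expect_identical(parameterCount(a), parameterCount(c))
  expect_false(identical(a@steps, c@steps))
})

test_that("parameter count grows with base channel width", {
  counts <- vapply(c(2, 4, 8), function(bc)
    parameterCount(buildFCRN(fcrnSpec(baseChannels = bc))), numeric(1))
  expect_true(all(diff(counts) > 0))
  countsU <- vapply(c(2, 4, 8), function(bc)
    parameterCount(buildUNet(unetSpec(baseChannels = bc))), numeric(1))
  expect_true(all(diff(countsU) > 0))
})

test_that("forward obeys shape, batching, divisibility and finiteness", {
  net <- buildUNet(unetSpec(baseChannels = 2), initSeed = 2)
  imgs <- lapply(1:4, function(i) matrix(runif(64 * 64), 64, 64))
  out <- predictDensity(net, imgs)
  expect_length(out, 4)
  expect_true(all(vapply(out, function(m) all(dim(m) == 64), logical(1))))
  # identical inputs give identical outputs
  expect_identical(predictDensity(net, imgs[[1]]),
                   predictDensity(net, imgs[[1]]))
  # all-zero input stays finite
  expect_true(all(is.finite(predictDensity(net, matrix(0, 64, 64)))))
  # indivisible shapes name the required divisor
  expect_error(predictDensity(net, matrix(0, 60, 60)), "divisible by 8")
})

test_that("relu output heads produce non-negative maps", {
  net <- buildFCRN(fcrnSpec(baseChannels = 2, outputActivation = "relu"),
                   initSeed = 3)
  out <- predictDensity(net, matrix(runif(32 * 32), 32, 32))
  expect_true(all(out >= 0))
})

test_that("analytic gradients match finite differences", {
  eng <- asNamespace("dropcount")
  set.seed(21)
  for (spec in list(fcrnSpec(baseChannels = 2, outputActivation = "linear"),
                    unetSpec(baseChannels = 2, outputActivation = "linear"))) {
    net <- buildNetwork(spec, initSeed = 5)
    x <- array(rnorm(64), c(8, 8, 1))
    t <- matrix(rnorm(64), 8, 8)
    res <- eng$.cppBatchPass(net@steps, list(x), list(t), 1 / 64)
    lossAt <- function(steps) {
      y <- eng$.forwardSteps(steps, x)$out
      mean((matrix(y, 8, 8) - t)^2)
    }
    for (si in which(!vapply(res$grads, is.null, logical(1)))[c(1, 3)]) {
      for (ix in sample(length(net@steps[[si]]$W), 3)) {
        eps <- 1e-6
        up <- net@steps; up[[si]]$W[ix] <- up[[si]]$W[ix] + eps
        dn <- net@steps; dn[[si]]$W[ix] <- dn[[si]]$W[ix] - eps
        num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
        expect_equal(res$grads[[si]]$gW[ix], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("the fused batch pass matches the reference R walker", {
  eng <- asNamespace("dropcount")
  set.seed(8)
  net <- buildUNet(unetSpec(baseChannels = 2), initSeed = 8)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  t <- matrix(rnorm(16 * 16), 16, 16)
  fused <- eng$.cppBatchPass(net@steps, list(x), list(t), 1 / 256)
  fw <- eng$.forwardSteps(net@steps, x, wantCache = TRUE)
  resid <- matrix(fw$out, 16, 16) - t
  ref <- eng$.backwardSteps(net@steps, fw$cache,
                            eng$.asCube(2 * resid / 256))
  expect_equal(fused$loss[1], mean(resid^2), tolerance = 1e-12)
  for (si in seq_along(ref)) {
    if (is.null(ref[[si]])) next
    expect_equal(fused$grads[[si]]$gW, ref[[si]]$gW, tolerance = 1e-10)
    expect_equal(as.numeric(fused$grads[[si]]$gb),
                 as.numeric(ref[[si]]$gb),
                 tolerance = 1e-10)
  }
})

test_that("checkpoints round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".rds")
  net <- buildFCRN(fcrnSpec(baseChannels = 2), initSeed = 6)
  saveCheckpoint(net, path)
  back <- loadCheckpoint(path)
  expect_identical(back@steps, net@steps)
  expect_identical(parameterCount(back), parameterCount(net))
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predictDensity(back, img), predictDensity(net, img))
  expect_error(saveCheckpoint(net, path, force = FALSE), "exists")
  expect_error(loadCheckpoint(withr::local_tempfile()), "not found")
})
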