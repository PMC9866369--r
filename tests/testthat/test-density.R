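test_that("kernel normalization contracts hold", {
  kp <- gaussianKernel(KernelSpec(sigma = 2, truncationRadius = 6,
                                  normalization = "unit_peak"))
  expect_identical(max(kp), 1)              # peak scaled to exactly 1
  expect_equal(kp[7, 7], 1)                 # ... at the center
  ki <- gaussianKernel(KernelSpec(sigma = 2, truncationRadius = 6))
  expect_lt(abs(sum(ki) - 1), 1e-9)
  expect_equal(which(ki == max(ki)), 85L)   # center of a 13 x 13 grid
})

test_that("kernel matches the closed-form Gaussian ratio", {
  k <- gaussianKernel(KernelSpec(sigma = 1, truncationRadius = 4))
  c0 <- k[5, 5]
  expect_equal(k[5, 6] / c0, exp(-1 / 2))
  expect_equal(k[6, 6] / c0, exp(-1))
})

test_that("kernels are symmetric under flips and transposition", {
  for (sig in c(1, 2.5)) {
    k <- gaussianKernel(KernelSpec(sigma = sig, truncationRadius = 5))
    expect_identical(k, t(k))
    expect_identical(k, k[nrow(k):1, ])
    expect_identical(k, k[, ncol(k):1])
  }
  expect_error(KernelSpec(sigma = 0), "sigma")
  expect_error(KernelSpec(sigma = 1, truncationRadius = 0),
               "truncationRadius")
})

test_that("density maps superpose one kernel per dot", {
  kern <- KernelSpec(sigma = 2, truncationRadius = 8)

  empty <- buildDensityMap(DotAnnotation(matrix(numeric(0), 0, 2),
                                         c(40, 40)), kern)
  expect_equal(densityValues(empty), matrix(0, 40, 40))
  expect_identical(empty@sourceCount, 0L)

  one <- buildDensityMap(DotAnnotation(rbind(c(20, 20)), c(41, 41)), kern)
  expect_lt(abs(sum(densityValues(one)) - 1), 1e-6)

  # two dots one pixel apart under unit_peak superpose above 1; the
  # explicit two-kernel sum is the oracle
  kpk <- KernelSpec(sigma = 2, truncationRadius = 8,
                    normalization = "unit_peak")
  two <- buildDensityMap(DotAnnotation(rbind(c(20, 20), c(20, 21)),
                                       c(41, 41)), kpk)
  K <- gaussianKernel(kpk)
  oracle <- matrix(0, 41, 41)
  oracle[13:29, 13:29] <- oracle[13:29, 13:29] + K
  oracle[13:29, 14:30] <- oracle[13:29, 14:30] + K
  expect_equal(densityValues(two), oracle)
  expect_gt(max(densityValues(two)), 1)
})

test_that("count recovery is calibrated in both normalization modes", {
  set.seed(4)
  for (mode in c("unit_integral", "unit_peak")) {
    kern <- KernelSpec(sigma = 2, truncationRadius = 8,
                       normalization = mode)
    ann <- randomAnnotation(7, margin = 8)
    cnt <- countFromDensity(buildDensityMap(ann, kern))
    expect_lt(abs(cnt - 7), 1e-6)
  }
  zero <- DensityMap(matrix(0, 8, 8), KernelSpec())
  expect_identical(countFromDensity(zero), 0)
})

test_that("regional counts integrate subregions and tile the frame", {
  kern <- KernelSpec(sigma = 1.5, truncationRadius = 6)
  # symmetric two-dot scene: one dot per lateral half
  ann <- DotAnnotation(rbind(c(31.6, 15), c(31.6, 48)), c(64, 64))
  map <- buildDensityMap(ann, kern)

  expect_equal(countInRegion(map, c(0, 63), c(0, 63)),
               countFromDensity(map))
  expect_lt(abs(countInRegion(map, c(0, 63), c(0, 31)) - 1), 1e-3)
  expect_lt(abs(countInRegion(map, c(0, 63), c(32, 63)) - 1), 1e-3)
  expect_lt(countInRegion(map, c(0, 7), c(22, 41)), 1e-9)  # far from dots

  tiles <- sum(countInRegion(map, c(0, 31), c(0, 31)),
               countInRegion(map, c(0, 31), c(32, 63)),
               countInRegion(map, c(32, 63), c(0, 31)),
               countInRegion(map, c(32, 63), c(32, 63)))
  expect_lt(abs(tiles - countFromDensity(map)), 1e-9)

  expect_error(countInRegion(map, c(0, 64), c(0, 63)), "region")
})

test_that("density maps agree with the naive summation oracle", {
  set.seed(11)
  for (mode in c("unit_integral", "unit_peak")) {
    kern <- KernelSpec(sigma = 2, truncationRadius = 6,
                       normalization = mode)
    for (rep in 1:3) {
      ann <- randomAnnotation(sample(0:10, 1), H = 48, W = 40)
      got <- densityValues(buildDensityMap(ann, kern))
      want <- naiveDensity(dotPoints(ann), c(48, 40), 2, 6, mode)
      expect_lt(max(abs(got - want)), 1e-8)
    }
  }
})

test_that("moving a dot toward the border never increases the count", {
  kern <- KernelSpec(sigma = 2, truncationRadius = 8)
  counts <- vapply(seq(32, 0, by = -2), function(r) {
    countFromDensity(buildDensityMap(DotAnnotation(rbind(c(r, 32)),
                                                   c(64, 64)), kern))
  }, numeric(1))
  expect_true(all(diff(counts) <= 1e-12))
})

test_that("density flip equivariance is exact", {
  kern <- KernelSpec(sigma = 2)
  cfg <- smallSceneConfig(countRange = c(4, 10))
  for (s in 1:5) {
    sc <- generateScene(cfg, s)
    direct <- densityValues(buildDensityMap(annotation(sc), kern))
    flipped <- buildDensityMap(annotation(augmentSample(sc, "hflip")), kern)
    expect_identical(densityValues(flipped), direct[, ncol(direct):1])
    flippedV <- buildDensityMap(annotation(augmentSample(sc, "vflip")), kern)
    expect_identical(densityValues(flippedV), direct[nrow(direct):1, ])
  }
})
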