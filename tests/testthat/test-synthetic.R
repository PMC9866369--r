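test_that("scene generation honors count range, margin and zero case", {
  cfg0 <- smallSceneConfig(countRange = c(0, 0))
  expect_equal(dotCount(generateScene(cfg0, 1)), 0)

  cfg12 <- smallSceneConfig(countRange = c(12, 12))
  for (s in c(1, 9, 77)) {
    sc <- generateScene(cfg12, s)
    expect_equal(dotCount(sc), 12)
    p <- dotPoints(sc)
    expect_true(all(p >= 4 & p[, 1] <= 63 - 4 & p[, 2] <= 63 - 4))
  }

  cfg <- smallSceneConfig(countRange = c(2, 9))
  counts <- vapply(1:40, function(s) dotCount(generateScene(cfg, s)),
                   numeric(1))
  expect_true(all(counts >= 2 & counts <= 9))
  expect_gt(length(unique(counts)), 1)
})

test_that("scene generation is deterministic in (config, seed)", {
  cfg <- smallSceneConfig()
  a <- generateScene(cfg, 7)
  b <- generateScene(cfg, 7)
  expect_identical(pixelGrid(a), pixelGrid(b))
  expect_identical(dotPoints(a), dotPoints(b))
  expect_false(identical(pixelGrid(a), pixelGrid(generateScene(cfg, 8))))
})

test_that("grain centers are brighter than the grain-free background", {
  # same scene seed with countRange (0,0) reproduces the identical
  # background + noise, so the pixel difference isolates the grain layer
  cfg <- smallSceneConfig(countRange = c(5, 10))
  bare <- smallSceneConfig(countRange = c(0, 0))
  for (s in c(3, 14, 15)) {
    sc <- generateScene(cfg, s)
    bg <- generateScene(bare, s)
    p <- round(dotPoints(sc)) + 1
    expect_true(all(pixelGrid(sc)[p] > pixelGrid(bg)[p]))
  }
})

test_that("invalid scene configs name the offending field", {
  expect_error(SceneConfig(countRange = c(5, 2)), "countRange")
  expect_error(SceneConfig(grainIntensityRange = c(0.2, 1.4)),
               "grainIntensityRange")
  expect_error(SceneConfig(minCenterMargin = 200), "minCenterMargin")
  expect_error(SceneConfig(noiseSd = -0.1), "noiseSd")
})

test_that("generateDataset writes images, annotations and a manifest", {
  dir <- withr::local_tempdir()
  cfg <- smallSceneConfig(seed = 11)
  manifest <- generateDataset(cfg, 5, dir)
  expect_equal(nrow(manifest), 5)
  expect_length(list.files(dir, pattern = "\\.png$"), 5)
  expect_length(list.files(dir, pattern = "\\.csv$"), 5)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  # regeneration is byte-identical
  before <- lapply(list.files(dir, full.names = TRUE), readBin,
                   what = "raw", n = 1e6)
  generateDataset(cfg, 5, dir)
  after <- lapply(list.files(dir, full.names = TRUE), readBin,
                  what = "raw", n = 1e6)
  expect_identical(before, after)

  # counts recorded in the manifest match the annotations on disk
  loaded <- loadAnnotatedImages(dir)
  expect_equal(vapply(loaded, dotCount, numeric(1)), manifest$count)
})

test_that("dataset counts follow the configured uniform range", {
  dir <- withr::local_tempdir()
  cfg <- smallSceneConfig(seed = 5, countRange = c(5, 30))
  manifest <- generateDataset(cfg, 200, dir)
  expect_lt(abs(mean(manifest$count) - 17.5), 3)
})

test_that("dot annotation CSVs round-trip to at least 6 decimals", {
  path <- withr::local_tempfile(fileext = ".csv")
  pts <- cbind(runif(9, 0, 63.9), runif(9, 0, 63.9))
  ann <- DotAnnotation(pts, c(64, 64))
  writeDotAnnotation(ann, path)
  back <- readDotAnnotation(path, c(64, 64))
  expect_equal(dotPoints(back), dotPoints(ann), tolerance = 1e-7)
  expect_identical(readLines(path)[1], "row,col")
})

test_that("marker-image dot extraction finds component centroids", {
  img <- array(0, c(32, 32, 3))
  paint <- function(img, rows, cols) {
    img[rows, cols, 1] <- 1; img[rows, cols, 2] <- 0; img[rows, cols, 3] <- 0
    img
  }
  img <- paint(img, 3:4, 3:4)
  img <- paint(img, 10:11, 20:21)
  img <- paint(img, 25:26, 7:8)
  ann <- extractDotsFromMarkerImage(img)
  expect_equal(dotCount(ann), 3)
  # centroids in row-major discovery order, 0-based coordinates
  expect_equal(dotPoints(ann)[, "row"], c(2.5, 9.5, 24.5))
  expect_equal(dotPoints(ann)[, "col"], c(2.5, 19.5, 6.5))

  expect_equal(dotCount(extractDotsFromMarkerImage(array(0, c(8, 8, 3)))), 0)
})

test_that("diagonally touching markers merge under 8-connectivity", {
  img <- array(0, c(16, 16, 3))
  img[3:4, 3:4, 1] <- 1
  img[5:6, 5:6, 1] <- 1      # touches the first square only at a corner
  ann <- extractDotsFromMarkerImage(img)
  mask <- img[, , 1] > 0.9
  expect_equal(dotCount(ann), igraphComponentCount(mask))
  expect_equal(dotCount(ann), 1)
})

test_that("marker extraction agrees with the component oracle on noise", {
  set.seed(31)
  for (rep in 1:5) {
    mask <- matrix(runif(24 * 24) < 0.12, 24, 24)
    img <- array(0, c(24, 24, 3))
    img[, , 1][mask] <- 1
    ann <- extractDotsFromMarkerImage(img)
    expect_equal(dotCount(ann), igraphComponentCount(mask))
  }
})
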