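# Independent oracles and shared fixture builders used across test files.

# Naive density evaluation: for every pixel, sum the bivariate Gaussian of
# every (snapped) dot directly, with explicit loops and explicit truncation.
# Deliberately ignorant of how buildDensityMap composes kernels.
naiveDensity <- function(points, frameShape, sigma, r, normalization) {
  H <- frameShape[1]; W <- frameShape[2]
  off <- (-r):r
  norm <- switch(normalization,
                 unit_integral = sum(outer(exp(-off^2 / (2 * sigma^2)),
                                           exp(-off^2 / (2 * sigma^2)))),
                 unit_peak = 1)
  D <- matrix(0, H, W)
  if (nrow(points) == 0) return(D)
  for (k in seq_len(nrow(points))) {
    r0 <- min(max(round(points[k, 1]), 0), H - 1)
    c0 <- min(max(round(points[k, 2]), 0), W - 1)
    for (i in 0:(H - 1)) {
      for (j in 0:(W - 1)) {
        if (abs(i - r0) <= r && abs(j - c0) <= r) {
          D[i + 1, j + 1] <- D[i + 1, j + 1] +
            exp(-((i - r0)^2 + (j - c0)^2) / (2 * sigma^2)) / norm
        }
      }
    }
  }
  D
}

# 8-connectivity component count oracle built on igraph, independent of the
# package's flood-fill labeling.
igraphComponentCount <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  H <- nrow(mask)
  pos <- cbind((idx - 1) %% H, (idx - 1) %/% H)
  edges <- integer(0)
  if (length(idx) > 1) {
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1)) {
        if (max(abs(pos[a, ] - pos[b, ])) <= 1)
          edges <- c(edges, a, b)
      }
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::components(g)$no
}

# Small scene family used throughout: 64 x 64 frames, sparse small grains;
# any SceneConfig argument can be overridden.
smallSceneConfig <- function(seed = 1, countRange = c(3, 8), ...) {
  args <- modifyList(list(imageHeight = 64, imageWidth = 64,
                          countRange = countRange,
                          grainAxisRange = c(1.5, 3), minCenterMargin = 4,
                          seed = seed),
                     list(...))
  do.call(SceneConfig, args)
}

# Random annotation on an H x W frame with dots at least `margin` from
# every border.
randomAnnotation <- function(n, H = 64, W = 64, margin = 0) {
  pts <- cbind(runif(n, margin, H - 1 - margin),
               runif(n, margin, W - 1 - margin))
  DotAnnotation(pts, c(H, W))
}

# A network whose every parameter is zero: predicts the all-zero map.
zeroNetwork <- function(spec = unetSpec(baseChannels = 2)) {
  net <- buildNetwork(spec, initSeed = 1)
  net@steps <- lapply(net@steps, function(s) {
    if (!is.null(s$W)) { s$W[] <- 0; s$b[] <- 0 }
    s
  })
  net
}
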