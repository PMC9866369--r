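## Training protocol: random 80/20 split, online flip augmentation, center
## patches, per-patch mean/sd normalization, momentum SGD with a step-decay
## learning rate, MSE loss against (scaled) Gaussian density targets.

#' Randomly split sample identifiers into train and test sets
#'
#' @param x character vector of identifiers, a manifest data.frame with an
#'   `identifier` column, or a list of [AnnotatedImage-class] objects.
#' @param trainFraction fraction assigned to training;
#'   `|train| = round(trainFraction * N)`, clamped so neither side is
#'   empty.
#' @param seed split seed; identical seeds give identical splits.
#' @return `list(train = ..., test = ...)` of identifiers -- a disjoint,
#'   exhaustive partition.
#' @export
splitDataset <- function(x, trainFraction = 0.8, seed = 1) {
  ids <- if (is.character(x)) x
         else if (is.data.frame(x)) x$identifier
         else vapply(x, function(s) s@identifier, character(1))
  N <- length(ids)
  if (N < 2) stop("need at least 2 samples to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  nTrain <- min(max(round(trainFraction * N), 1), N - 1)
  idx <- .withSeed(seed, sample(N, nTrain))
  list(train = ids[sort(idx)], test = ids[sort(setdiff(seq_len(N), idx))])
}

#' Flip-augment an annotated sample
#'
#' Flips the pixel grid along the stated axis and maps every dot by the
#' same flip (`hflip`: col -> width - 1 - col; `vflip`:
#' row -> height - 1 - row). Counts are unchanged.
#'
#' @param sample an [AnnotatedImage-class].
#' @param mode `"none"`, `"hflip"` or `"vflip"`.
#' @return the augmented [AnnotatedImage-class].
#' @export
augmentSample <- function(sample, mode = c("none", "hflip", "vflip")) {
  mode <- match.arg(mode)
  if (mode == "none") return(sample)
  px <- sample@pixels
  p <- sample@annotation@points
  fs <- sample@annotation@frameShape
  if (mode == "hflip") {
    px <- if (length(dim(px)) == 3) px[, dim(px)[2]:1, , drop = FALSE]
          else px[, dim(px)[2]:1, drop = FALSE]
    if (nrow(p)) p[, 2] <- fs[2] - 1 - p[, 2]
  } else {
    px <- if (length(dim(px)) == 3) px[dim(px)[1]:1, , , drop = FALSE]
          else px[dim(px)[1]:1, , drop = FALSE]
    if (nrow(p)) p[, 1] <- fs[1] - 1 - p[, 1]
  }
  AnnotatedImage(px, DotAnnotation(p, fs), identifier = sample@identifier)
}

#' Extract the central square patch of a sample
#'
#' Returns the centered `patchSize x patchSize` window; dots outside the
#' window are dropped and retained dots are re-expressed in window
#' coordinates.
#'
#' @param sample an [AnnotatedImage-class] at least `patchSize` in both
#'   dimensions.
#' @param patchSize side length in pixels.
#' @return an [AnnotatedImage-class] of the stated size.
#' @export
extractCenterPatch <- function(sample, patchSize) {
  d <- dim(sample@pixels)
  if (d[1] < patchSize || d[2] < patchSize)
    stop(sprintf("image (%d x %d) is smaller than the requested %d px patch",
                 d[1], d[2], patchSize))
  if (d[1] == patchSize && d[2] == patchSize) return(sample)
  r0 <- floor((d[1] - patchSize) / 2)     # 0-based window origin
  c0 <- floor((d[2] - patchSize) / 2)
  px <- if (length(d) == 3)
          sample@pixels[r0 + seq_len(patchSize), c0 + seq_len(patchSize), ,
                        drop = FALSE]
        else sample@pixels[r0 + seq_len(patchSize), c0 + seq_len(patchSize),
                           drop = FALSE]
  p <- sample@annotation@points
  if (nrow(p)) {
    keep <- p[, 1] >= r0 & p[, 1] < r0 + patchSize &
            p[, 2] >= c0 & p[, 2] < c0 + patchSize
    p <- p[keep, , drop = FALSE]
    p[, 1] <- p[, 1] - r0
    p[, 2] <- p[, 2] - c0
  }
  AnnotatedImage(px, DotAnnotation(p, c(patchSize, patchSize)),
                 identifier = sample@identifier)
}

#' Standardize a patch to zero mean and unit standard deviation
#'
#' The per-patch normalization applied to every image before it enters a
#' network. Constant patches (sd = 0) map to all zeros.
#'
#' @param pixels numeric matrix or array.
#' @return grid of the same shape with mean 0 and sd 1 (or all zeros).
#' @export
normalizePatch <- function(pixels) {
  if (length(pixels) == 0) stop("empty patch")
  s <- sd(as.vector(pixels))
  if (!is.finite(s) || s == 0) return(pixels * 0)
  (pixels - mean(pixels)) / s
}

#' Learning rate at a given epoch under the step-decay schedule
#'
#' `learningRate / lrDecayFactor^floor(epoch / lrDecayEvery)` -- with the
#' defaults, 0.01 for epochs 0-9, 0.001 for 10-19, and so on.
#'
#' @param config a [TrainConfig-class].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return the learning rate, a positive scalar.
#' @export
lrAtEpoch <- function(config, epoch) {
  if (any(epoch < 0 | epoch >= config@epochs))
    stop(sprintf("epoch must lie in [0, %d)", as.integer(config@epochs)))
  config@learningRate / config@lrDecayFactor^floor(epoch / config@lrDecayEvery)
}

# Precompute (normalized input cube, scaled target matrix) for one sample.
.prepareSample <- function(sample, kernel, config) {
  d <- dim(sample@pixels)
  if (d[1] > config@patchSize || d[2] > config@patchSize)
    sample <- extractCenterPatch(sample, config@patchSize)
  x <- normalizePatch(.toGray(sample@pixels))
  t <- buildDensityMap(sample@annotation, kernel)@values * config@targetScale
  list(x = x, t = t)
}

#' Train a network to regress density surfaces
#'
#' Minimizes the mean squared error between predicted and target density
#' maps with momentum SGD, L2 weight decay, and the [lrAtEpoch()] step
#' schedule. Each epoch visits all samples in a seeded shuffled order in
#' minibatches of `config@batchSize`; when `config@augmentFlips` is on, one
#' of \{none, hflip, vflip\} is drawn per sample per epoch and applied to
#' image and target alike. Targets are the [buildDensityMap()] surfaces
#' scaled by `config@targetScale`; inputs are center-cropped to
#' `config@patchSize` if larger and passed through [normalizePatch()]. All
#' randomness (shuffling, augmentation) derives from `config@seed`, so a
#' run is exactly reproducible.
#'
#' @param network a [NetworkHandle-class] to train (left unmodified; the
#'   trained network is returned inside the log).
#' @param samples list of [AnnotatedImage-class] objects, or a manifest
#'   accepted by [loadAnnotatedImages()].
#' @param kernel the [KernelSpec-class] defining the density targets.
#' @param config a [TrainConfig-class].
#' @param verbose log per-epoch loss to stderr.
#' @return a [TrainLog-class] with per-epoch mean loss, per-epoch learning
#'   rate, and the trained network (`trainedNetwork()`).
#' @export
trainNetwork <- function(network, samples, kernel, config, verbose = FALSE) {
  validObject(config)
  if (is.character(samples) || is.data.frame(samples))
    samples <- loadAnnotatedImages(samples)
  n <- length(samples)
  if (n == 0) stop("training set is empty")
  prep <- lapply(samples, .prepareSample, kernel = kernel, config = config)
  d <- dim(prep[[1]]$x)
  .checkDivisible(network, d[1], d[2])
  nPix <- prod(d)

  steps <- network@steps
  velocity <- .zeroVelocity(steps)
  epochs <- as.integer(config@epochs)
  lossSeq <- numeric(epochs)
  lrSeq <- numeric(epochs)
  modes <- c("none", "hflip", "vflip")

  .withSeed(config@seed, {
    for (ep in seq_len(epochs) - 1L) {
      lr <- lrAtEpoch(config, ep)
      lrSeq[ep + 1L] <- lr
      order <- sample(n)
      epochLoss <- 0
      done <- 0L
      while (done < n) {
        take <- order[(done + 1L):min(n, done + config@batchSize)]
        xs <- vector("list", length(take))
        ts <- vector("list", length(take))
        for (bi in seq_along(take)) {
          x <- prep[[take[bi]]]$x
          t <- prep[[take[bi]]]$t
          if (config@augmentFlips) {
            mode <- modes[sample.int(3L, 1L)]
            if (mode == "hflip") {
              x <- x[, ncol(x):1]; t <- t[, ncol(t):1]
            } else if (mode == "vflip") {
              x <- x[nrow(x):1, ]; t <- t[nrow(t):1, ]
            }
          }
          xs[[bi]] <- .asCube(x)
          ts[[bi]] <- t
        }
        res <- .cppBatchPass(steps, xs, ts, 1 / (nPix * length(take)))
        epochLoss <- epochLoss + sum(res$loss)
        upd <- .sgdStep(steps, res$grads, velocity, lr, config@momentum,
                        config@weightDecay)
        steps <- upd$steps
        velocity <- upd$velocity
        done <- done + length(take)
      }
      lossSeq[ep + 1L] <- epochLoss / n
      if (!is.finite(lossSeq[ep + 1L]))
        stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
      if (verbose)
        .logMsg("INFO", "epoch %d/%d lr %.2g loss %.6g", ep + 1L, epochs,
                lr, lossSeq[ep + 1L])
    }
  })

  trained <- new("NetworkHandle", spec = network@spec, steps = steps,
                 parameterCount = network@parameterCount,
                 inputChannels = network@inputChannels)
  new("TrainLog", epochLoss = lossSeq, epochLr = lrSeq, network = trained)
}

#' Extract the trained network from a training log
#'
#' @param log a [TrainLog-class].
#' @return the trained [NetworkHandle-class].
#' @export
trainedNetwork <- function(log) log@network
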