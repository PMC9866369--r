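## The two regression architectures: an FCRN variant and a U-Net variant.
## Both are encoder-decoder networks with same-padded convolutions so the
## predicted density map keeps the input's spatial shape; all convolution
## parameters use seedable orthogonal initialization and biases start at 0.

#' Build the FCRN-variant density regressor
#'
#' A VGG-style fully convolutional regression network. Downsampling block
#' `i` (1-based) stacks `i` convolution+ReLU layers and ends in 2x2 max
#' pooling; the first block uses the larger allowed kernel (default 5x5),
#' later blocks the smaller (3x3). Channel counts start at
#' `spec@baseChannels` and multiply by `spec@channelGrowth` per level. A 1x1
#' convolution bottleneck (a fully connected layer applied convolutionally)
#' follows the last pool. Each of the `nBlocks` upsampling units is a 2x2
#' stride-2 transposed convolution, ReLU, then a convolution. A final 1x1
#' convolution maps to the single-channel density output, passed through
#' ReLU when `spec@outputActivation == "relu"`.
#'
#' @param spec an [ArchitectureSpec-class] with `family = "fcrn"`.
#' @param inputChannels image channels the network expects (default 1).
#' @param initSeed seed for the orthogonal initialization; identical
#'   `(spec, initSeed)` builds are identical.
#' @return a [NetworkHandle-class].
#' @examples
#' net <- buildFCRN(fcrnSpec(baseChannels = 4), initSeed = 1)
#' parameterCount(net)
#' @export
buildFCRN <- function(spec, inputChannels = 1, initSeed = 1) {
  validObject(spec)
  if (spec@family != "fcrn")
    stop("buildFCRN requires an ArchitectureSpec with family 'fcrn'")
  B <- spec@nBlocks
  kBig <- max(spec@kernelSizes); kSmall <- min(spec@kernelSizes)
  steps <- .withSeed(initSeed, {
    st <- list()
    ch <- inputChannels
    for (i in seq_len(B)) {
      k <- if (i == 1) kBig else kSmall
      cout <- spec@baseChannels * spec@channelGrowth^(i - 1)
      for (l in seq_len(i)) {
        st <- c(st, list(.convStep(k, ch, cout), list(op = "relu")))
        ch <- cout
      }
      st <- c(st, list(list(op = "pool")))
    }
    cb <- spec@baseChannels * spec@channelGrowth^B
    st <- c(st, list(.convStep(1, ch, cb), list(op = "relu")))
    ch <- cb
    for (j in rev(seq_len(B))) {
      cout <- spec@baseChannels * spec@channelGrowth^(j - 1)
      st <- c(st, list(.upconvStep(ch, cout), list(op = "relu"),
                       .convStep(kSmall, cout, cout)))
      ch <- cout
    }
    st <- c(st, list(.convStep(1, ch, 1, gain = 1)))
    if (spec@outputActivation == "relu")
      st <- c(st, list(list(op = "relu")))
    st
  })
  new("NetworkHandle", spec = spec, steps = steps,
      parameterCount = .countParams(steps), inputChannels = inputChannels)
}

#' Build the U-Net-variant density regressor
#'
#' A U-Net with `nBlocks` contracting blocks (two 3x3 convolution+ReLU
#' layers, then 2x2 max pooling), a two-convolution bridge, and `nBlocks`
#' expanding blocks (2x2 stride-2 up-convolution, concatenation with the
#' same-resolution contracting features via a skip connection, then two 3x3
#' convolution+ReLU layers). A final 1x1 convolution maps to one channel.
#'
#' @inheritParams buildFCRN
#' @param spec an [ArchitectureSpec-class] with `family = "unet"`.
#' @return a [NetworkHandle-class].
#' @export
buildUNet <- function(spec, inputChannels = 1, initSeed = 1) {
  validObject(spec)
  if (spec@family != "unet")
    stop("buildUNet requires an ArchitectureSpec with family 'unet'")
  B <- spec@nBlocks
  k <- min(spec@kernelSizes)
  steps <- .withSeed(initSeed, {
    st <- list()
    ch <- inputChannels
    for (i in seq_len(B)) {
      ci <- spec@baseChannels * spec@channelGrowth^(i - 1)
      st <- c(st, list(.convStep(k, ch, ci), list(op = "relu"),
                       .convStep(k, ci, ci), list(op = "relu"),
                       list(op = "save", slot = i),
                       list(op = "pool")))
      ch <- ci
    }
    cb <- spec@baseChannels * spec@channelGrowth^B
    st <- c(st, list(.convStep(k, ch, cb), list(op = "relu"),
                     .convStep(k, cb, cb), list(op = "relu")))
    ch <- cb
    for (j in rev(seq_len(B))) {
      cj <- spec@baseChannels * spec@channelGrowth^(j - 1)
      st <- c(st, list(.upconvStep(ch, cj),
                       list(op = "concat", slot = j),
                       .convStep(k, 2 * cj, cj), list(op = "relu"),
                       .convStep(k, cj, cj), list(op = "relu")))
      ch <- cj
    }
    st <- c(st, list(.convStep(1, ch, 1, gain = 1)))
    if (spec@outputActivation == "relu")
      st <- c(st, list(list(op = "relu")))
    st
  })
  new("NetworkHandle", spec = spec, steps = steps,
      parameterCount = .countParams(steps), inputChannels = inputChannels)
}

#' @rdname buildFCRN
#' @export
buildNetwork <- function(spec, inputChannels = 1, initSeed = 1) {
  switch(spec@family,
         fcrn = buildFCRN(spec, inputChannels, initSeed),
         unet = buildUNet(spec, inputChannels, initSeed))
}

.checkDivisible <- function(network, H, W) {
  div <- 2^network@spec@nBlocks
  if (H %% div != 0 || W %% div != 0)
    stop(sprintf("input spatial dims (%d x %d) must be divisible by %d for %d pooling levels",
                 H, W, div, network@spec@nBlocks))
}

#' Predict density maps from images
#'
#' Runs the network forward. Input pixel grids are used as given (apply
#' [normalizePatch()] first to match the training-time contract); RGB
#' images are collapsed to luminance when the network expects one channel.
#'
#' @param network a [NetworkHandle-class].
#' @param images a single image (matrix or H x W x 3 array) or a list of
#'   them; spatial dims must be divisible by `2^nBlocks`.
#' @return a density-map-shaped matrix per input image (a list when a list
#'   was given). Deterministic given fixed parameters; all values are
#'   non-negative under the default `"relu"` output activation.
#' @export
predictDensity <- function(network, images) {
  single <- !is.list(images)
  if (single) images <- list(images)
  out <- lapply(images, function(im) {
    if (network@inputChannels == 1) im <- .toGray(im)
    x <- .asCube(im)
    .checkDivisible(network, dim(x)[1], dim(x)[2])
    y <- .forwardSteps(network@steps, x)$out
    matrix(y, dim(y)[1], dim(y)[2])
  })
  if (single) out[[1]] else out
}
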