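## Central S4 classes. Coordinates are 0-based (row, col) reals, row
## increasing downward; a point is inside an H x W frame iff it lies in
## [0, H) x [0, W). Pixel intensities live in [0, 1].

.checkRange <- function(x, field, lo = NULL, hi = NULL) {
  if (length(x) != 2 || any(!is.finite(x)))
    return(sprintf("%s must be two finite numbers", field))
  if (x[1] > x[2])
    return(sprintf("%s must satisfy min <= max", field))
  if (!is.null(lo) && x[1] < lo)
    return(sprintf("%s lower bound must be >= %g", field, lo))
  if (!is.null(hi) && x[2] > hi)
    return(sprintf("%s upper bound must be <= %g", field, hi))
  NULL
}

#' SceneConfig: parameters of the synthetic dropping-scene generator
#'
#' Describes the family of synthetic scenes the generator draws from:
#' frame size, how many grain-like blobs to place, their size and
#' brightness, the background gray level, a linear illumination gradient,
#' pixel noise, and how far blob centers stay from the frame border.
#'
#' @slot imageHeight,imageWidth frame size in pixels.
#' @slot countRange inclusive integer interval for grains per scene.
#' @slot grainAxisRange min/max semi-axes of the elliptical blobs (pixels).
#' @slot grainIntensityRange relative brightness lift of a grain over the
#'   background, in \[0, 1\].
#' @slot backgroundLevelRange base background gray level interval in \[0, 1\].
#' @slot illuminationGradientMax maximum relative linear shading across the
#'   frame (0 disables the gradient).
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot minCenterMargin minimum distance (pixels) of any dot from every
#'   border.
#' @slot seed master seed; per-scene seeds are derived from it.
#' @export
setClass("SceneConfig",
  representation(
    imageHeight = "numeric", imageWidth = "numeric",
    countRange = "numeric", grainAxisRange = "numeric",
    grainIntensityRange = "numeric", backgroundLevelRange = "numeric",
    illuminationGradientMax = "numeric", noiseSd = "numeric",
    minCenterMargin = "numeric", seed = "numeric"
  ),
  validity = function(object) {
    msgs <- c(
      if (object@imageHeight < 1 || object@imageWidth < 1)
        "imageHeight/imageWidth must be >= 1",
      .checkRange(object@countRange, "countRange", lo = 0),
      .checkRange(object@grainAxisRange, "grainAxisRange", lo = 0.5),
      .checkRange(object@grainIntensityRange, "grainIntensityRange", 0, 1),
      .checkRange(object@backgroundLevelRange, "backgroundLevelRange", 0, 1),
      if (object@illuminationGradientMax < 0)
        "illuminationGradientMax must be >= 0",
      if (object@noiseSd < 0) "noiseSd must be >= 0",
      if (object@minCenterMargin < 0 ||
          object@minCenterMargin >= min(object@imageHeight,
                                        object@imageWidth) / 2)
        "minCenterMargin must be >= 0 and < min(height, width)/2"
    )
    if (length(msgs)) msgs else TRUE
  })

#' @param imageHeight,imageWidth,countRange,grainAxisRange,grainIntensityRange
#'   see slots.
#' @param backgroundLevelRange,illuminationGradientMax,noiseSd,minCenterMargin,seed
#'   see slots.
#' @rdname SceneConfig-class
#' @export
SceneConfig <- function(imageHeight = 256, imageWidth = 256,
                        countRange = c(5, 60), grainAxisRange = c(2, 5),
                        grainIntensityRange = c(0.25, 0.6),
                        backgroundLevelRange = c(0.2, 0.5),
                        illuminationGradientMax = 0.3, noiseSd = 0.02,
                        minCenterMargin = 4, seed = 1) {
  new("SceneConfig", imageHeight = imageHeight, imageWidth = imageWidth,
      countRange = countRange, grainAxisRange = grainAxisRange,
      grainIntensityRange = grainIntensityRange,
      backgroundLevelRange = backgroundLevelRange,
      illuminationGradientMax = illuminationGradientMax, noiseSd = noiseSd,
      minCenterMargin = minCenterMargin, seed = seed)
}

#' DotAnnotation: point labels marking object centers
#'
#' One real-valued (row, col) coordinate per labeled object. The number of
#' points is the ground-truth object count.
#'
#' @slot points numeric matrix with columns `row`, `col`; may have 0 rows.
#' @slot frameShape `c(height, width)` of the annotated frame, in pixels.
#' @export
setClass("DotAnnotation",
  representation(points = "matrix", frameShape = "numeric"),
  validity = function(object) {
    p <- object@points
    fs <- object@frameShape
    if (length(fs) != 2 || any(fs < 1))
      return("frameShape must be c(height, width), both >= 1")
    if (ncol(p) != 2) return("points must have two columns (row, col)")
    if (nrow(p) > 0) {
      if (any(!is.finite(p))) return("points must be finite")
      if (any(p[, 1] < 0 | p[, 1] >= fs[1]))
        return("point rows must lie in [0, height)")
      if (any(p[, 2] < 0 | p[, 2] >= fs[2]))
        return("point cols must lie in [0, width)")
    }
    TRUE
  })

#' @param points numeric matrix (n x 2) of 0-based (row, col) coordinates.
#' @param frameShape `c(height, width)` in pixels.
#' @rdname DotAnnotation-class
#' @export
DotAnnotation <- function(points, frameShape) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  new("DotAnnotation", points = points, frameShape = as.numeric(frameShape))
}

#' AnnotatedImage: a pixel grid plus its dot annotation
#'
#' @slot pixels numeric matrix (H x W) or array (H x W x 3) with values in
#'   \[0, 1\].
#' @slot annotation a [DotAnnotation-class] whose frame matches the pixels.
#' @slot identifier free-form sample id.
#' @export
setClass("AnnotatedImage",
  representation(pixels = "ANY", annotation = "DotAnnotation",
                 identifier = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (is.null(d) || !(length(d) %in% c(2, 3)))
      return("pixels must be a matrix or an H x W x 3 array")
    if (length(d) == 3 && d[3] != 3)
      return("3-d pixels must have exactly 3 channels")
    if (!isTRUE(all(object@pixels >= -1e-9 & object@pixels <= 1 + 1e-9)))
      return("pixel values must lie in [0, 1]")
    if (!isTRUE(all(object@annotation@frameShape == d[1:2])))
      return("annotation frameShape must equal the pixel grid's shape")
    TRUE
  })

#' @param pixels,annotation,identifier see slots.
#' @rdname AnnotatedImage-class
#' @export
AnnotatedImage <- function(pixels, annotation, identifier = "") {
  new("AnnotatedImage", pixels = pixels, annotation = annotation,
      identifier = identifier)
}

#' KernelSpec: the Gaussian kernel placed on each annotated dot
#'
#' An isotropic Gaussian with spread `sigma`, truncated to a
#' `(2r + 1) x (2r + 1)` support. Two normalizations are supported:
#' `"unit_integral"` scales entries to sum to 1, so each dot contributes
#' exactly one unit of mass to the density surface; `"unit_peak"` scales the
#' kernel maximum to exactly 1, in which case counting divides the summed
#' density by the analytic mass of one unit-peak kernel.
#'
#' @slot sigma Gaussian spread in pixels (> 0).
#' @slot truncationRadius integer support half-width r (>= 1; >= 3 sigma
#'   recommended so that truncation loses negligible mass).
#' @slot normalization `"unit_integral"` or `"unit_peak"`.
#' @export
setClass("KernelSpec",
  representation(sigma = "numeric", truncationRadius = "numeric",
                 normalization = "character"),
  validity = function(object) {
    msgs <- c(
      if (!is.finite(object@sigma) || object@sigma <= 0)
        "sigma must be a positive number",
      if (object@truncationRadius < 1 ||
          object@truncationRadius != round(object@truncationRadius))
        "truncationRadius must be an integer >= 1",
      if (!object@normalization %in% c("unit_integral", "unit_peak"))
        "normalization must be 'unit_integral' or 'unit_peak'"
    )
    if (length(msgs)) msgs else TRUE
  })

#' @param sigma,truncationRadius,normalization see slots. The default radius
#'   is `ceiling(4 * sigma)`.
#' @rdname KernelSpec-class
#' @export
KernelSpec <- function(sigma = 2, truncationRadius = ceiling(4 * sigma),
                       normalization = c("unit_integral", "unit_peak")) {
  new("KernelSpec", sigma = sigma, truncationRadius = truncationRadius,
      normalization = match.arg(normalization))
}

#' DensityMap: a non-negative density surface over a pixel grid
#'
#' @slot values numeric matrix of non-negative densities, same shape as the
#'   source image.
#' @slot kernel the [KernelSpec-class] the map was built (or should be
#'   interpreted) under.
#' @slot sourceCount number of dots used to build the map, or `NA` for
#'   predicted maps.
#' @export
setClass("DensityMap",
  representation(values = "matrix", kernel = "KernelSpec",
                 sourceCount = "integer"),
  validity = function(object) {
    if (any(object@values < -1e-12))
      return("density values must be non-negative")
    TRUE
  })

#' @param values,kernel,sourceCount see slots.
#' @rdname DensityMap-class
#' @export
DensityMap <- function(values, kernel, sourceCount = NA_integer_) {
  new("DensityMap", values = values, kernel = kernel,
      sourceCount = as.integer(sourceCount))
}

#' ArchitectureSpec: declarative description of a regression network
#'
#' Both families are encoder-decoder networks with `nBlocks` downsampling
#' and `nBlocks` upsampling stages operating at matched resolutions, so the
#' predicted density map has the same spatial shape as the input.
#'
#' @slot family `"fcrn"` or `"unet"`.
#' @slot nBlocks number of downsampling blocks (= upsampling blocks).
#' @slot kernelSizes allowed odd convolution sizes. The FCRN uses the
#'   largest in its first block and the smallest elsewhere; the U-Net uses
#'   the smallest throughout.
#' @slot baseChannels feature maps in the first block.
#' @slot channelGrowth multiplier applied to the channel count per depth
#'   level.
#' @slot outputActivation `"linear"` (default; predicted maps are clamped
#'   at zero when counted) or `"relu"` (non-negative outputs by
#'   construction).
#' @export
setClass("ArchitectureSpec",
  representation(family = "character", nBlocks = "numeric",
                 kernelSizes = "numeric", baseChannels = "numeric",
                 channelGrowth = "numeric", outputActivation = "character"),
  validity = function(object) {
    msgs <- c(
      if (!object@family %in% c("fcrn", "unet"))
        "family must be 'fcrn' or 'unet'",
      if (object@nBlocks < 1 || object@nBlocks != round(object@nBlocks))
        "nBlocks must be an integer >= 1",
      if (any(object@kernelSizes < 1 | object@kernelSizes %% 2 != 1))
        "kernelSizes must be odd and >= 1",
      if (object@baseChannels < 1) "baseChannels must be >= 1",
      if (object@channelGrowth < 1) "channelGrowth must be >= 1",
      if (!object@outputActivation %in% c("linear", "relu"))
        "outputActivation must be 'linear' or 'relu'"
    )
    if (length(msgs)) msgs else TRUE
  })

#' @param family,nBlocks,kernelSizes,baseChannels,channelGrowth,outputActivation
#'   see slots.
#' @rdname ArchitectureSpec-class
#' @export
ArchitectureSpec <- function(family = c("fcrn", "unet"), nBlocks = 3,
                             kernelSizes = c(3, 5), baseChannels = 32,
                             channelGrowth = 2,
                             outputActivation = c("linear", "relu")) {
  new("ArchitectureSpec", family = match.arg(family), nBlocks = nBlocks,
      kernelSizes = sort(kernelSizes), baseChannels = baseChannels,
      channelGrowth = channelGrowth,
      outputActivation = match.arg(outputActivation))
}

#' @rdname ArchitectureSpec-class
#' @param ... passed on to [ArchitectureSpec()].
#' @export
fcrnSpec <- function(...) ArchitectureSpec(family = "fcrn", ...)

#' @rdname ArchitectureSpec-class
#' @export
unetSpec <- function(...) ArchitectureSpec(family = "unet", ...)

#' NetworkHandle: a built, trainable image-to-density network
#'
#' Produced by [buildFCRN()] / [buildUNet()]; holds the layer sequence with
#' its parameters. Treat it as opaque and use [predictDensity()],
#' [trainNetwork()], [saveCheckpoint()].
#'
#' @slot spec the [ArchitectureSpec-class] the network was built from.
#' @slot steps internal layer sequence with weights.
#' @slot parameterCount total number of trainable scalars (a pure function
#'   of the spec and input channel count).
#' @slot inputChannels number of input image channels.
#' @export
setClass("NetworkHandle",
  representation(spec = "ArchitectureSpec", steps = "list",
                 parameterCount = "numeric", inputChannels = "numeric"),
  validity = function(object) {
    if (object@parameterCount <= 0) return("parameterCount must be > 0")
    TRUE
  })

#' TrainConfig: the full training protocol
#'
#' Defaults follow the study protocol this package implements: SGD with
#' initial learning rate 0.01 divided by 10 every 10 epochs, momentum 0.8,
#' weight decay 0.005, MSE loss on density surfaces, an 80/20 random
#' train/test split, and online horizontal/vertical flip augmentation.
#'
#' @slot learningRate initial SGD step size.
#' @slot lrDecayFactor divisor applied to the learning rate at each decay.
#' @slot lrDecayEvery epochs between decays.
#' @slot momentum SGD momentum coefficient.
#' @slot weightDecay L2 penalty coefficient added to gradients.
#' @slot epochs training epochs.
#' @slot batchSize minibatch size (the study compares 1, 8, 16).
#' @slot trainFraction fraction of samples assigned to the training split.
#' @slot augmentFlips draw one of \{none, hflip, vflip\} per sample per epoch.
#' @slot patchSize side of the square center patch fed to the network.
#' @slot targetScale global factor applied to density targets so per-pixel
#'   magnitudes are well-conditioned for MSE; divided back out of predicted
#'   maps before counting.
#' @slot seed seed for split, shuffling, augmentation draws.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", lrDecayFactor = "numeric",
                 lrDecayEvery = "numeric", momentum = "numeric",
                 weightDecay = "numeric", epochs = "numeric",
                 batchSize = "numeric", trainFraction = "numeric",
                 augmentFlips = "logical", patchSize = "numeric",
                 targetScale = "numeric", seed = "numeric"),
  validity = function(object) {
    msgs <- c(
      if (object@learningRate <= 0) "learningRate must be > 0",
      if (object@lrDecayFactor <= 1) "lrDecayFactor must be > 1",
      if (object@lrDecayEvery < 1) "lrDecayEvery must be >= 1",
      if (object@momentum < 0 || object@momentum >= 1)
        "momentum must be in [0, 1)",
      if (object@weightDecay < 0) "weightDecay must be >= 0",
      if (object@epochs < 1) "epochs must be >= 1",
      if (object@batchSize < 1) "batchSize must be >= 1",
      if (object@trainFraction <= 0 || object@trainFraction >= 1)
        "trainFraction must be in (0, 1)",
      if (object@patchSize < 1) "patchSize must be >= 1",
      if (object@targetScale <= 0) "targetScale must be > 0"
    )
    if (length(msgs)) msgs else TRUE
  })

#' @param learningRate,lrDecayFactor,lrDecayEvery,momentum,weightDecay see
#'   slots.
#' @param epochs,batchSize,trainFraction,augmentFlips,patchSize,targetScale,seed
#'   see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(learningRate = 0.01, lrDecayFactor = 10,
                        lrDecayEvery = 10, momentum = 0.8,
                        weightDecay = 0.005, epochs = 200, batchSize = 1,
                        trainFraction = 0.8, augmentFlips = TRUE,
                        patchSize = 256, targetScale = 100, seed = 1) {
  new("TrainConfig", learningRate = learningRate,
      lrDecayFactor = lrDecayFactor, lrDecayEvery = lrDecayEvery,
      momentum = momentum, weightDecay = weightDecay, epochs = epochs,
      batchSize = batchSize, trainFraction = trainFraction,
      augmentFlips = augmentFlips, patchSize = patchSize,
      targetScale = targetScale, seed = seed)
}

#' TrainLog: per-epoch record of a training run
#'
#' @slot epochLoss mean training MSE per epoch.
#' @slot epochLr learning rate used in each epoch.
#' @slot network the trained [NetworkHandle-class].
#' @export
setClass("TrainLog",
  representation(epochLoss = "numeric", epochLr = "numeric",
                 network = "NetworkHandle"),
  validity = function(object) {
    if (length(object@epochLoss) != length(object@epochLr))
      return("epochLoss and epochLr must have equal length")
    if (any(object@epochLr <= 0)) return("learning rates must be positive")
    if (any(diff(object@epochLr) > 0))
      return("learning rates must be non-increasing")
    TRUE
  })

#' EvalReport: per-image counts with MAE/RMSE aggregates
#'
#' @slot records data.frame with columns `identifier`, `true_count`,
#'   `predicted_count`.
#' @slot mae mean absolute count error.
#' @slot rmse root mean squared count error (always >= mae).
#' @slot n number of evaluated images.
#' @export
setClass("EvalReport",
  representation(records = "data.frame", mae = "numeric", rmse = "numeric",
                 n = "numeric"),
  validity = function(object) {
    msgs <- c(
      if (object@mae < 0) "mae must be >= 0",
      if (object@rmse < object@mae - 1e-9) "rmse must be >= mae",
      if (object@n != nrow(object@records))
        "n must equal the number of records"
    )
    if (length(msgs)) msgs else TRUE
  })

#' RunConfig: nested configuration binding a whole pipeline run
#'
#' @slot scene a [SceneConfig-class].
#' @slot kernel a [KernelSpec-class].
#' @slot architecture an [ArchitectureSpec-class].
#' @slot training a [TrainConfig-class].
#' @slot paths named list: `data_dir`, `out_dir`, `checkpoint`.
#' @export
setClass("RunConfig",
  representation(scene = "SceneConfig", kernel = "KernelSpec",
                 architecture = "ArchitectureSpec", training = "TrainConfig",
                 paths = "list"))
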