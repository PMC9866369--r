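#' Accessors for dropcount classes
#'
#' Small accessor generics: `dotPoints()` returns the (row, col) coordinate
#' matrix of an annotation, `dotCount()` the number of annotated objects,
#' `frameShape()` the `c(height, width)` of the annotated frame,
#' `annotation()` the [DotAnnotation-class] of an [AnnotatedImage-class],
#' `pixelGrid()` its pixel matrix/array, `densityValues()` the value matrix
#' of a [DensityMap-class], and `parameterCount()` the number of trainable
#' scalars of a [NetworkHandle-class].
#'
#' @param x object to access.
#' @return see details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dotPoints", function(x) standardGeneric("dotPoints"))
#' @rdname accessors
#' @export
setGeneric("dotCount", function(x) standardGeneric("dotCount"))
#' @rdname accessors
#' @export
setGeneric("frameShape", function(x) standardGeneric("frameShape"))
#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setGeneric("pixelGrid", function(x) standardGeneric("pixelGrid"))
#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))

#' @rdname accessors
#' @export
setMethod("dotPoints", "DotAnnotation", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("dotPoints", "AnnotatedImage", function(x) x@annotation@points)
#' @rdname accessors
#' @export
setMethod("dotCount", "DotAnnotation", function(x) nrow(x@points))
#' @rdname accessors
#' @export
setMethod("dotCount", "AnnotatedImage", function(x) nrow(x@annotation@points))
#' @rdname accessors
#' @export
setMethod("frameShape", "DotAnnotation", function(x) x@frameShape)
#' @rdname accessors
#' @export
setMethod("frameShape", "AnnotatedImage", function(x) x@annotation@frameShape)
#' @rdname accessors
#' @export
setMethod("annotation", "AnnotatedImage", function(x) x@annotation)
#' @rdname accessors
#' @export
setMethod("pixelGrid", "AnnotatedImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("densityValues", "DensityMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("parameterCount", "NetworkHandle", function(x) x@parameterCount)

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px, %d-%d grains, axes %.1f-%.1f px\n",
              object@imageHeight, object@imageWidth,
              object@countRange[1], object@countRange[2],
              object@grainAxisRange[1], object@grainAxisRange[2]))
  cat(sprintf("  background %.2f-%.2f, lift %.2f-%.2f, shading <= %.2f, noise sd %.3f, margin %g px, seed %g\n",
              object@backgroundLevelRange[1], object@backgroundLevelRange[2],
              object@grainIntensityRange[1], object@grainIntensityRange[2],
              object@illuminationGradientMax, object@noiseSd,
              object@minCenterMargin, object@seed))
})

setMethod("show", "DotAnnotation", function(object) {
  cat(sprintf("DotAnnotation: %d dot(s) in a %g x %g frame\n",
              nrow(object@points), object@frameShape[1],
              object@frameShape[2]))
})

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("AnnotatedImage '%s': %d x %d%s, %d dot(s)\n",
              object@identifier, d[1], d[2],
              if (length(d) == 3) " x 3" else "",
              nrow(object@annotation@points)))
})

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec: sigma %g px, radius %g px, %s\n", object@sigma,
              object@truncationRadius, object@normalization))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap %d x %d (%s), integral count %.4f%s\n",
              nrow(object@values), ncol(object@values),
              object@kernel@normalization, countFromDensity(object),
              if (is.na(object@sourceCount)) ""
              else sprintf(", built from %d dot(s)", object@sourceCount)))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec: %s, %g down/up blocks, base %g channels (x%g per level), kernels {%s}, %s output\n",
              toupper(object@family), object@nBlocks, object@baseChannels,
              object@channelGrowth,
              paste(object@kernelSizes, collapse = ","),
              object@outputActivation))
})

setMethod("show", "NetworkHandle", function(object) {
  cat(sprintf("NetworkHandle: %s with %s trainable parameters (%g input channel(s))\n",
              toupper(object@spec@family),
              format(object@parameterCount, big.mark = ","),
              object@inputChannels))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: lr %g (/%g every %g epochs), momentum %g, weight decay %g\n",
              object@learningRate, object@lrDecayFactor, object@lrDecayEvery,
              object@momentum, object@weightDecay))
  cat(sprintf("  %g epochs, batch %g, train fraction %g, flips %s, patch %g px, target scale %g, seed %g\n",
              object@epochs, object@batchSize, object@trainFraction,
              object@augmentFlips, object@patchSize, object@targetScale,
              object@seed))
})

setMethod("show", "TrainLog", function(object) {
  n <- length(object@epochLoss)
  cat(sprintf("TrainLog: %d epoch(s), loss %.6g -> %.6g\n", n,
              object@epochLoss[1], object@epochLoss[n]))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: n = %g images, MAE = %.4f, RMSE = %.4f\n",
              object@n, object@mae, object@rmse))
})
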