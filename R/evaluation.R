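## Count evaluation: per-image predicted vs. true counts, MAE/RMSE, and the
## architecture-by-batch-size comparison harness.

#' Mean absolute error between true and predicted counts
#'
#' `mean(|x_i - y_i|)` over images.
#'
#' @param trueCounts,predictedCounts numeric vectors of equal, positive
#'   length.
#' @return non-negative scalar.
#' @examples
#' maeCounts(c(4, 7), c(3, 5))   # 1.5
#' @export
maeCounts <- function(trueCounts, predictedCounts) {
  .checkPairs(trueCounts, predictedCounts)
  mean(abs(trueCounts - predictedCounts))
}

#' Root mean squared error between true and predicted counts
#'
#' `sqrt(mean((x_i - y_i)^2))`; never smaller than [maeCounts()] on the
#' same pairs.
#'
#' @inheritParams maeCounts
#' @return non-negative scalar.
#' @export
rmseCounts <- function(trueCounts, predictedCounts) {
  .checkPairs(trueCounts, predictedCounts)
  sqrt(mean((trueCounts - predictedCounts)^2))
}

.checkPairs <- function(x, y) {
  if (length(x) == 0) stop("count list must be non-empty")
  if (length(x) != length(y))
    stop("true and predicted counts must have equal length")
}

#' Evaluate a trained network on a test set
#'
#' For each image: apply the training-time preprocessing (center patch,
#' luminance, [normalizePatch()]), run the network, divide the predicted
#' map by `config@targetScale`, and integrate it with [countFromDensity()].
#' Predicted counts are kept real-valued (not rounded).
#'
#' @param network a trained [NetworkHandle-class].
#' @param samples list of [AnnotatedImage-class] objects or a manifest.
#' @param kernel the [KernelSpec-class] used for training targets.
#' @param config the [TrainConfig-class] used in training (for `patchSize`
#'   and `targetScale`).
#' @return an [EvalReport-class].
#' @export
evaluateNetwork <- function(network, samples, kernel, config = TrainConfig()) {
  if (is.character(samples) || is.data.frame(samples))
    samples <- loadAnnotatedImages(samples)
  if (length(samples) == 0) stop("test set is empty")
  recs <- lapply(samples, function(s) {
    d <- dim(s@pixels)
    if (d[1] > config@patchSize || d[2] > config@patchSize)
      s <- extractCenterPatch(s, config@patchSize)
    x <- normalizePatch(.toGray(s@pixels))
    pred <- predictDensity(network, x) / config@targetScale
    map <- DensityMap(pmax(pred, 0), kernel)
    data.frame(identifier = s@identifier,
               true_count = dotCount(s),
               predicted_count = countFromDensity(map))
  })
  records <- do.call(rbind, recs)
  new("EvalReport", records = records,
      mae = maeCounts(records$true_count, records$predicted_count),
      rmse = rmseCounts(records$true_count, records$predicted_count),
      n = nrow(records))
}

#' Write an evaluation report to disk
#'
#' Writes the per-image records as CSV
#' (`identifier,true_count,predicted_count`) and the aggregates as JSON
#' (`mae`, `rmse`, `n`).
#'
#' @param report an [EvalReport-class].
#' @param csvPath,jsonPath output paths (either may be `NULL` to skip).
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.csv(report@records, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(mae = report@mae, rmse = report@rmse,
                              n = report@n),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Train-and-evaluate comparison across architectures and batch sizes
#'
#' Reproduces the study's comparison design on a given dataset: every
#' (family, batch size) cell is trained on the same train/test split with
#' the same initialization seed, so the cell effect is isolated, then
#' evaluated on the held-out test set.
#'
#' @param samples list of [AnnotatedImage-class] objects or a manifest.
#' @param families architecture families to compare.
#' @param batchSizes minibatch sizes to compare.
#' @param kernel the density-target [KernelSpec-class].
#' @param config base [TrainConfig-class]; `batchSize` is overridden per
#'   cell.
#' @param archSpecs named list of [ArchitectureSpec-class] per family
#'   (defaults to `fcrnSpec()` / `unetSpec()`).
#' @param outCsv optional path for the comparison table CSV (columns
#'   Network, Batch Size, MAE, RMSE).
#' @param verbose log progress to stderr.
#' @return data.frame with columns `family`, `batch_size`, `mae`, `rmse`;
#'   the all-zeros baseline MAE of the test split (the mean true count) is
#'   attached as attribute `"baseline_mae"`.
#' @export
runComparison <- function(samples, families = c("fcrn", "unet"),
                          batchSizes = c(1, 8, 16),
                          kernel = KernelSpec(), config = TrainConfig(),
                          archSpecs = NULL, outCsv = NULL,
                          verbose = FALSE) {
  if (is.character(samples) || is.data.frame(samples))
    samples <- loadAnnotatedImages(samples)
  if (is.null(archSpecs))
    archSpecs <- list(fcrn = fcrnSpec(), unet = unetSpec())
  split <- splitDataset(samples, config@trainFraction, config@seed)
  ids <- vapply(samples, function(s) s@identifier, character(1))
  trainSet <- samples[ids %in% split$train]
  testSet <- samples[ids %in% split$test]
  rows <- list()
  for (fam in families) {
    for (bs in batchSizes) {
      if (verbose) .logMsg("INFO", "training %s, batch size %d", fam, bs)
      cellCfg <- config
      cellCfg@batchSize <- bs
      net <- buildNetwork(archSpecs[[fam]], initSeed = config@seed)
      log <- trainNetwork(net, trainSet, kernel, cellCfg, verbose = verbose)
      rep <- evaluateNetwork(trainedNetwork(log), testSet, kernel, cellCfg)
      rows[[length(rows) + 1]] <-
        data.frame(family = fam, batch_size = bs, mae = rep@mae,
                   rmse = rep@rmse)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_mae") <-
    mean(vapply(testSet, dotCount, numeric(1)))
  if (!is.null(outCsv)) {
    tab <- data.frame(Network = toupper(out$family),
                      `Batch Size` = out$batch_size, MAE = out$mae,
                      RMSE = out$rmse, check.names = FALSE)
    write.csv(tab, outCsv, row.names = FALSE, quote = FALSE)
  }
  out
}
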