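## Synthetic dropping-like scenes with exact dot labels.
##
## A scene is composed from three independent seeded streams so that the
## background+noise of a scene is reproducible independently of how many
## grains are placed on it: (1) background -- base gray level, a linear
## illumination gradient of random direction, and a smooth coarse texture;
## (2) grains -- count, centers, elliptical shape, orientation, brightness
## lift; (3) additive pixel noise.

#' Generate one synthetic dot-annotated scene
#'
#' Draws a textured, unevenly lit background, places `k` bright elliptical
#' grain-like blobs (k uniform on `countRange`) with anti-aliased edges and
#' random orientation, adds Gaussian pixel noise, and records the exact blob
#' centers as the dot annotation. Identical `(config, sceneSeed)` pairs
#' reproduce the scene bit-for-bit; the caller's RNG state is untouched.
#'
#' @param config a [SceneConfig-class].
#' @param sceneSeed integer seed for this scene.
#' @param identifier sample id stored in the result.
#' @return an [AnnotatedImage-class] whose annotation has one point per
#'   rendered blob, each at least `minCenterMargin` pixels from every
#'   border.
#' @examples
#' sc <- generateScene(SceneConfig(imageHeight = 64, imageWidth = 64,
#'                                 countRange = c(3, 6)), sceneSeed = 7)
#' dotCount(sc)
#' @export
generateScene <- function(config, sceneSeed, identifier = NULL) {
  validObject(config)
  H <- config@imageHeight; W <- config@imageWidth
  if (is.null(identifier)) identifier <- sprintf("scene_seed%d", sceneSeed)

  bg <- .withSeed(.deriveSeed(sceneSeed, 1), .renderBackground(config))
  gr <- .withSeed(.deriveSeed(sceneSeed, 2), .renderGrains(config))
  noise <- .withSeed(.deriveSeed(sceneSeed, 3),
                     matrix(rnorm(H * W, 0, config@noiseSd), H, W))

  pixels <- pmin(pmax(bg + noise + gr$layer, 0), 1)
  AnnotatedImage(pixels,
                 DotAnnotation(gr$centers, c(H, W)),
                 identifier = identifier)
}

# Background field in [0, 0.85]: base level * (1 + shading) + texture.
# Capping below 1 guarantees grain centers stay strictly brighter than the
# grain-free background even after the final clamp to [0, 1].
.renderBackground <- function(config) {
  H <- config@imageHeight; W <- config@imageWidth
  level <- runif(1, config@backgroundLevelRange[1],
                 config@backgroundLevelRange[2])
  theta <- runif(1, 0, 2 * pi)
  mag <- runif(1, 0, config@illuminationGradientMax)
  xn <- if (W > 1) seq(-1, 1, length.out = W) else 0
  yn <- if (H > 1) seq(-1, 1, length.out = H) else 0
  proj <- outer(yn * sin(theta), xn * cos(theta), "+")
  nrm <- abs(sin(theta)) + abs(cos(theta))
  shading <- mag * proj / nrm
  gh <- ceiling(H / 16) + 1; gw <- ceiling(W / 16) + 1
  texture <- .bilinearUpsample(matrix(runif(gh * gw, -1, 1), gh, gw), H, W)
  pmin(pmax(level * (1 + shading) + 0.08 * level * texture, 0), 0.85)
}

# Additive grain layer plus the exact centers used.
.renderGrains <- function(config) {
  H <- config@imageHeight; W <- config@imageWidth
  lo <- config@countRange[1]; hi <- config@countRange[2]
  k <- lo + sample.int(hi - lo + 1, 1) - 1
  layer <- matrix(0, H, W)
  if (k == 0)
    return(list(layer = layer, centers = matrix(numeric(0), 0, 2)))
  m <- config@minCenterMargin
  rows <- runif(k, m, H - 1 - m)
  cols <- runif(k, m, W - 1 - m)
  a <- runif(k, config@grainAxisRange[1], config@grainAxisRange[2])
  b <- runif(k, config@grainAxisRange[1], config@grainAxisRange[2])
  ang <- runif(k, 0, pi)
  lift <- runif(k, config@grainIntensityRange[1],
                config@grainIntensityRange[2])
  for (g in seq_len(k)) {
    rad <- max(a[g], b[g]) + 1.5
    i0 <- max(0, floor(rows[g] - rad)); i1 <- min(H - 1, ceiling(rows[g] + rad))
    j0 <- max(0, floor(cols[g] - rad)); j1 <- min(W - 1, ceiling(cols[g] + rad))
    dr <- (i0:i1) - rows[g]
    dc <- (j0:j1) - cols[g]
    u <- outer(dr * sin(ang[g]), dc * cos(ang[g]), "+")
    v <- outer(dr * cos(ang[g]), -dc * sin(ang[g]), "+")
    d <- sqrt((u / a[g])^2 + (v / b[g])^2)
    cov <- pmin(pmax((1 - d) * min(a[g], b[g]) + 0.5, 0), 1)
    layer[i0:i1 + 1, j0:j1 + 1] <- layer[i0:i1 + 1, j0:j1 + 1] +
      lift[g] * cov
  }
  list(layer = layer, centers = cbind(rows, cols))
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes one 8-bit grayscale PNG and one dot-annotation CSV (header
#' `row,col`, one line per dot) per scene, plus a JSON manifest listing
#' `identifier`, `image_path`, `annotation_path` (relative to `outDir`) and
#' `count`. Scene seeds are derived deterministically as
#' `config@seed + scene index`, so regenerating with the same config is
#' byte-identical.
#'
#' @param config a [SceneConfig-class].
#' @param nImages number of scenes (>= 1).
#' @param outDir output directory (created if needed).
#' @return the manifest as a data.frame, invisibly.
#' @seealso [readManifest()], [loadAnnotatedImages()]
#' @export
generateDataset <- function(config, nImages, outDir) {
  validObject(config)
  if (nImages < 1) stop("nImages must be >= 1")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  records <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    id <- sprintf("scene_%04d", i)
    scene <- generateScene(config, sceneSeed = config@seed + i,
                           identifier = id)
    imgRel <- paste0(id, ".png"); annRel <- paste0(id, ".csv")
    png::writePNG(scene@pixels, file.path(outDir, imgRel))
    writeDotAnnotation(scene@annotation, file.path(outDir, annRel))
    records[[i]] <- data.frame(identifier = id, image_path = imgRel,
                               annotation_path = annRel,
                               count = dotCount(scene))
  }
  manifest <- do.call(rbind, records)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset manifest written by [generateDataset()]
#'
#' @param path path to a `manifest.json` (or the directory containing one).
#' @return data.frame with columns `identifier`, `image_path`,
#'   `annotation_path`, `count`; paths are resolved against the manifest's
#'   directory and returned absolute.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  m$image_path <- file.path(base, m$image_path)
  m$annotation_path <- file.path(base, m$annotation_path)
  m
}

#' Load annotated images listed in a manifest
#'
#' @param manifest data.frame from [readManifest()], or a path accepted by
#'   it.
#' @return list of [AnnotatedImage-class] objects.
#' @export
loadAnnotatedImages <- function(manifest) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    pixels <- png::readPNG(manifest$image_path[i])
    if (length(dim(pixels)) == 3 && dim(pixels)[3] > 3)
      pixels <- pixels[, , 1:3]          # drop alpha
    ann <- readDotAnnotation(manifest$annotation_path[i],
                             frameShape = dim(pixels)[1:2])
    AnnotatedImage(pixels, ann, identifier = manifest$identifier[i])
  })
}

#' Write / read a dot annotation as CSV
#'
#' The canonical annotation format: a CSV with header `row,col` and one line
#' per dot, 0-based real-valued pixel coordinates. Round-trips preserve
#' coordinates to at least 6 decimal places.
#'
#' @param annotation a [DotAnnotation-class].
#' @param path CSV file path.
#' @export
writeDotAnnotation <- function(annotation, path) {
  df <- as.data.frame(annotation@points)
  colnames(df) <- c("row", "col")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param frameShape `c(height, width)` of the annotated frame.
#' @rdname writeDotAnnotation
#' @export
readDotAnnotation <- function(path, frameShape) {
  df <- read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("annotation CSV must have columns 'row' and 'col'")
  DotAnnotation(cbind(df$row, df$col), frameShape)
}

#' Extract dot annotations from a marker (red-dot) image
#'
#' Field annotations are often burned into an image as colored dots. This
#' groups all pixels within a per-channel tolerance of `markerColor` into
#' 8-connected components and returns one dot per component at its centroid,
#' in row-major order of component discovery.
#'
#' @param markerPixels H x W x 3 array in \[0, 1\] (values in 0..255 are
#'   rescaled).
#' @param markerColor RGB triple of the marker, same scale conventions;
#'   default pure red.
#' @param tolerance maximum per-channel distance, on the \[0, 1\] scale
#'   (default 10/255).
#' @return a [DotAnnotation-class]; empty when no pixel matches.
#' @export
extractDotsFromMarkerImage <- function(markerPixels,
                                       markerColor = c(1, 0, 0),
                                       tolerance = 10 / 255) {
  d <- dim(markerPixels)
  if (length(d) != 3 || d[3] < 3) stop("marker image must be RGB")
  if (max(markerPixels) > 1) markerPixels <- markerPixels / 255
  if (max(markerColor) > 1) markerColor <- markerColor / 255
  H <- d[1]; W <- d[2]
  mask <- abs(markerPixels[, , 1] - markerColor[1]) <= tolerance &
          abs(markerPixels[, , 2] - markerColor[2]) <= tolerance &
          abs(markerPixels[, , 3] - markerColor[3]) <= tolerance
  comps <- .labelComponents8(mask)
  if (length(comps) == 0)
    return(DotAnnotation(matrix(numeric(0), 0, 2), c(H, W)))
  centroids <- t(vapply(comps, function(px) {
    c(mean((px - 1) %% H), mean((px - 1) %/% H))   # 0-based (row, col)
  }, numeric(2)))
  DotAnnotation(centroids, c(H, W))
}

# 8-connected component labeling by stack-based flood fill; returns a list
# of linear pixel index vectors in row-major discovery order.
.labelComponents8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (i in seq_len(H)) {           # row-major scan
    for (j in seq_len(W)) {
      if (!mask[i, j] || seen[i, j]) next
      stack <- (j - 1) * H + i
      seen[i, j] <- TRUE
      members <- integer(0)
      while (length(stack)) {
        p <- stack[length(stack)]; stack <- stack[-length(stack)]
        members <- c(members, p)
        pi <- (p - 1) %% H + 1; pj <- (p - 1) %/% H + 1
        for (di in -1:1) for (dj in -1:1) {
          ni <- pi + di; nj <- pj + dj
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
              mask[ni, nj] && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            stack <- c(stack, (nj - 1) * H + ni)
          }
        }
      }
      comps[[length(comps) + 1]] <- members
    }
  }
  comps
}
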