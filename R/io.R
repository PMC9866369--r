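## File formats: NPY export of density maps, heat-map PNGs, checkpoints.

#' Export / import a density map as a single-array NPY file
#'
#' Writes the value matrix as a 32-bit float array in NPY format (version
#' 1.0, C order), readable by any NPY consumer. The float32 round trip is
#' exact to single precision only.
#'
#' @param map a [DensityMap-class] or a plain numeric matrix.
#' @param path output file.
#' @export
writeDensityMap <- function(map, path) {
  m <- if (is(map, "DensityMap")) map@values else map
  H <- nrow(m); W <- ncol(m)
  header <- sprintf("{'descr': '<f4', 'fortran_order': False, 'shape': (%d, %d), }",
                    H, W)
  total <- 10 + nchar(header) + 1
  pad <- (64 - total %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' @param kernel optional [KernelSpec-class] to attach to the imported map;
#'   when omitted a plain matrix is returned.
#' @rdname writeDensityMap
#' @export
readDensityMap <- function(path, kernel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  shape <- as.integer(strsplit(sub(".*'shape': \\(([0-9, ]+)\\).*", "\\1",
                                   header), ",")[[1]])
  descr <- sub(".*'descr': '([^']+)'.*", "\\1", header)
  size <- if (grepl("f8", descr)) 8L else 4L
  fortran <- grepl("'fortran_order': True", header)
  vals <- readBin(con, "numeric", prod(shape), size = size,
                  endian = "little")
  m <- if (fortran) matrix(vals, shape[1], shape[2])
       else t(matrix(vals, shape[2], shape[1]))
  if (is.null(kernel)) m else DensityMap(pmax(m, 0), kernel)
}

#' Write a density map as an 8-bit heat-map PNG
#'
#' Visualization only (lossy): values are scaled by the map maximum and
#' mapped through an inferno-like palette.
#'
#' @param map a [DensityMap-class] or numeric matrix.
#' @param path output PNG path.
#' @export
writeHeatmapPNG <- function(map, path) {
  m <- if (is(map, "DensityMap")) map@values else map
  mx <- max(m)
  scaled <- if (mx > 0) m / mx else m
  pal <- grDevices::colorRamp(grDevices::hcl.colors(256, "inferno"))
  rgb <- pal(as.vector(scaled)) / 255
  img <- array(rgb, dim = c(nrow(m), ncol(m), 3))
  png::writePNG(img, path)
  invisible(path)
}

#' Save / load a network checkpoint
#'
#' Serializes a [NetworkHandle-class] (architecture spec plus all weights)
#' to a single file; loading reconstructs the handle bit-exactly, so a
#' saved and reloaded network produces identical predictions.
#'
#' @param network a [NetworkHandle-class].
#' @param path checkpoint file.
#' @param force overwrite an existing file.
#' @export
saveCheckpoint <- function(network, path, force = TRUE) {
  if (file.exists(path) && !force)
    stop("checkpoint exists (use force = TRUE to overwrite): ", path)
  s <- network@spec
  payload <- list(
    format = "dropcount-checkpoint-1",
    spec = list(family = s@family, nBlocks = s@nBlocks,
                kernelSizes = s@kernelSizes, baseChannels = s@baseChannels,
                channelGrowth = s@channelGrowth,
                outputActivation = s@outputActivation),
    inputChannels = network@inputChannels,
    steps = network@steps)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  p <- readRDS(path)
  if (!identical(p$format, "dropcount-checkpoint-1"))
    stop("not a dropcount checkpoint: ", path)
  spec <- ArchitectureSpec(family = p$spec$family, nBlocks = p$spec$nBlocks,
                           kernelSizes = p$spec$kernelSizes,
                           baseChannels = p$spec$baseChannels,
                           channelGrowth = p$spec$channelGrowth,
                           outputActivation = p$spec$outputActivation)
  new("NetworkHandle", spec = spec, steps = p$steps,
      parameterCount = .countParams(p$steps),
      inputChannels = p$inputChannels)
}
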