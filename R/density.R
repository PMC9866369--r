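## Gaussian density targets and counting by integration.
##
## Each annotated dot contributes one truncated isotropic Gaussian; the
## superposition is the density surface the networks regress. Under
## unit-integral normalization every interior dot contributes exactly one
## unit of mass, so the count is the plain sum of the map. Under unit-peak
## normalization (kernel maximum scaled to exactly 1) the sum is divided by
## the analytic mass of a single unit-peak kernel, restoring the
## one-dot-one-count calibration.

#' Evaluate a truncated isotropic Gaussian kernel
#'
#' Returns the `(2r + 1) x (2r + 1)` grid of
#' `exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))` centered at the grid
#' middle, scaled according to `spec@normalization`: entries summing to 1
#' (`"unit_integral"`) or a center value of exactly 1 (`"unit_peak"`).
#'
#' @param spec a [KernelSpec-class].
#' @return numeric matrix; symmetric under flips and transposition, maximum
#'   at the center.
#' @examples
#' K <- gaussianKernel(KernelSpec(sigma = 2, truncationRadius = 6))
#' sum(K)
#' @export
gaussianKernel <- function(spec) {
  validObject(spec)
  r <- spec@truncationRadius
  g1 <- exp(-((-r):r)^2 / (2 * spec@sigma^2))
  K <- outer(g1, g1)                  # center value exactly 1
  switch(spec@normalization,
         unit_integral = K / sum(K),
         unit_peak = K)
}

#' Analytic mass of one unit-peak kernel
#'
#' The sum of a single truncated unit-peak Gaussian; the divisor that turns
#' summed unit-peak density into a count. Equals 1 for unit-integral
#' kernels.
#'
#' @param spec a [KernelSpec-class].
#' @return positive scalar.
#' @export
kernelMass <- function(spec) {
  if (spec@normalization == "unit_integral") return(1)
  r <- spec@truncationRadius
  sum(exp(-((-r):r)^2 / (2 * spec@sigma^2)))^2
}

#' Build the ground-truth density map of a dot annotation
#'
#' Sums one kernel per dot, centered at the dot's nearest integer pixel and
#' truncated at the frame border (clipped kernels are not renormalized, so
#' a dot within `truncationRadius` of the border contributes slightly less
#' than full mass).
#'
#' @param annotation a [DotAnnotation-class].
#' @param kernel a [KernelSpec-class].
#' @return a [DensityMap-class]; an empty annotation yields an all-zero map.
#' @examples
#' ann <- DotAnnotation(rbind(c(32, 32)), c(64, 64))
#' sum(densityValues(buildDensityMap(ann, KernelSpec(sigma = 2))))
#' @export
buildDensityMap <- function(annotation, kernel) {
  validObject(annotation); validObject(kernel)
  H <- annotation@frameShape[1]; W <- annotation@frameShape[2]
  D <- matrix(0, H, W)
  n <- nrow(annotation@points)
  if (n > 0) {
    K <- gaussianKernel(kernel)
    r <- kernel@truncationRadius
    for (i in seq_len(n)) {
      p <- annotation@points[i, ]
      if (p[1] < 0 || p[1] >= H || p[2] < 0 || p[2] >= W)
        stop(sprintf("dot %d at (%g, %g) lies outside the %g x %g frame",
                     i, p[1], p[2], H, W))
      r0 <- min(max(round(p[1]), 0), H - 1)   # snap to pixel, 0-based
      c0 <- min(max(round(p[2]), 0), W - 1)
      ri <- max(0, r0 - r):min(H - 1, r0 + r)
      ci <- max(0, c0 - r):min(W - 1, c0 + r)
      D[ri + 1, ci + 1] <- D[ri + 1, ci + 1] +
        K[ri - r0 + r + 1, ci - c0 + r + 1]
    }
  }
  DensityMap(D, kernel, sourceCount = n)
}

#' Recover an object count by integrating a density map
#'
#' Sums all entries; for unit-peak maps the sum is divided by
#' [kernelMass()] so that one isolated interior dot yields a count of 1.
#'
#' @param map a [DensityMap-class].
#' @return non-negative real count estimate.
#' @export
countFromDensity <- function(map) {
  sum(map@values) / kernelMass(map@kernel)
}

#' Count objects within a rectangular subregion
#'
#' Integrating the density over a window estimates the number of objects in
#' that window; a disjoint tiling of the frame sums to [countFromDensity()].
#'
#' @param map a [DensityMap-class].
#' @param rows,cols inclusive 0-based index ranges `c(first, last)` of the
#'   window.
#' @return mass-corrected sum over the window.
#' @export
countInRegion <- function(map, rows, cols) {
  H <- nrow(map@values); W <- ncol(map@values)
  if (length(rows) != 2 || length(cols) != 2 ||
      rows[1] < 0 || rows[2] >= H || cols[1] < 0 || cols[2] >= W ||
      rows[1] > rows[2] || cols[1] > cols[2])
    stop(sprintf("region must satisfy 0 <= first <= last within a %d x %d frame",
                 H, W))
  sum(map@values[(rows[1]:rows[2]) + 1, (cols[1]:cols[2]) + 1, drop = FALSE]) /
    kernelMass(map@kernel)
}
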