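## Internal helpers shared across modules.

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream seed from (seed, k); kept in 32-bit integer range.
.deriveSeed <- function(seed, k) {
  as.integer((abs(seed) + k * 1000003) %% 2147483647)
}

# Collapse RGB to a single luminance channel; pass matrices through.
.toGray <- function(pixels) {
  if (length(dim(pixels)) == 3)
    0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  else pixels
}

# Separable bilinear upsampling of a coarse grid to (H, W).
.bilinearUpsample <- function(g, H, W) {
  interpMat <- function(n, m) {
    M <- matrix(0, n, m)
    if (m == 1) { M[, 1] <- 1; return(M) }
    t <- seq(0, 1, length.out = n) * (m - 1)
    i0 <- pmin(floor(t), m - 2)
    f <- t - i0
    M[cbind(seq_len(n), i0 + 1)] <- 1 - f
    M[cbind(seq_len(n), i0 + 2)] <- M[cbind(seq_len(n), i0 + 2)] + f
    M
  }
  interpMat(H, nrow(g)) %*% g %*% t(interpMat(W, ncol(g)))
}

.logMsg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...)))
}
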