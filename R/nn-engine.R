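## Internal conv-net engine. A network is a flat sequence of steps:
##   conv    same-padded convolution, weights (kh*kw*cin x cout)
##   relu    elementwise max(0, x)
##   pool    2x2 max pooling, stride 2
##   upconv  2x2 stride-2 transposed convolution, weights (cin x 4*cout)
##   save    stash the current activation in a numbered slot
##   concat  append a stashed activation along the channel axis
## Heavy kernels live in src/nn_ops.cpp (im2col + GEMM); the R layer only
## sequences them and owns the parameter updates.

# Orthogonal initialization (QR of a Gaussian matrix, sign-corrected),
# scaled by `gain`; draws from the current RNG stream.
.orthoInit <- function(nr, nc, gain) {
  n <- max(nr, nc); m <- min(nr, nc)
  qrA <- qr(matrix(rnorm(n * m), n, m))
  Q <- qr.Q(qrA) %*% diag(sign(diag(qr.R(qrA))), m, m)
  gain * (if (nr >= nc) Q else t(Q))
}

.convStep <- function(k, cin, cout, gain = sqrt(2)) {
  list(op = "conv", kh = k, kw = k, cin = cin, cout = cout,
       W = .orthoInit(k * k * cin, cout, gain), b = numeric(cout))
}

.upconvStep <- function(cin, cout, gain = sqrt(2)) {
  list(op = "upconv", cin = cin, cout = cout,
       W = .orthoInit(cin, 4 * cout, gain), b = numeric(cout))
}

.countParams <- function(steps) {
  sum(vapply(steps, function(s)
    if (!is.null(s$W)) length(s$W) + length(s$b) else 0, numeric(1)))
}

.asCube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# Forward pass. Returns list(out, cache); cache holds what backward needs.
.forwardSteps <- function(steps, x, wantCache = FALSE) {
  cache <- if (wantCache) vector("list", length(steps)) else NULL
  saved <- list()
  for (si in seq_along(steps)) {
    s <- steps[[si]]
    x <- switch(s$op,
      conv = {
        if (wantCache) cache[[si]] <- x
        .cppConvForward(x, s$W, s$b, s$kh, s$kw)
      },
      relu = {
        if (wantCache) cache[[si]] <- x
        pmax(x, 0)
      },
      pool = {
        r <- .cppPoolForward(x)
        if (wantCache) cache[[si]] <- list(idx = r$idx, H = dim(x)[1],
                                           W = dim(x)[2])
        r$y
      },
      upconv = {
        if (wantCache) cache[[si]] <- x
        .cppUpconvForward(x, s$W, s$b)
      },
      save = {
        saved[[s$slot]] <- x
        x
      },
      concat = {
        own <- dim(x)[3]
        if (wantCache) cache[[si]] <- own
        array(c(x, saved[[s$slot]]),
              dim = c(dim(x)[1], dim(x)[2], own + dim(saved[[s$slot]])[3]))
      },
      stop("unknown step op: ", s$op))
  }
  list(out = x, cache = cache)
}

# Backward pass; returns per-step list(gW, gb) aligned with `steps`.
.backwardSteps <- function(steps, cache, gout) {
  grads <- vector("list", length(steps))
  gslot <- list()
  g <- gout
  for (si in rev(seq_along(steps))) {
    s <- steps[[si]]
    g <- switch(s$op,
      conv = {
        r <- .cppConvBackward(cache[[si]], s$W, g, s$kh, s$kw)
        grads[[si]] <- list(gW = r$gW, gb = r$gb)
        r$gx
      },
      relu = g * (cache[[si]] > 0),
      pool = .cppPoolBackward(g, cache[[si]]$idx, cache[[si]]$H,
                              cache[[si]]$W),
      upconv = {
        r <- .cppUpconvBackward(cache[[si]], s$W, g)
        grads[[si]] <- list(gW = r$gW, gb = r$gb)
        r$gx
      },
      save = {
        if (!is.null(gslot[[s$slot]])) g + gslot[[s$slot]] else g
      },
      concat = {
        own <- cache[[si]]
        tot <- dim(g)[3]
        gslot[[s$slot]] <- g[, , (own + 1):tot, drop = FALSE]
        g[, , seq_len(own), drop = FALSE]
      })
  }
  grads
}

.zeroGrads <- function(steps) {
  lapply(steps, function(s)
    if (!is.null(s$W)) list(gW = array(0, dim(s$W)), gb = numeric(length(s$b)))
    else NULL)
}

.addGrads <- function(acc, g) {
  for (i in seq_along(acc)) {
    if (!is.null(acc[[i]]) && !is.null(g[[i]])) {
      acc[[i]]$gW <- acc[[i]]$gW + g[[i]]$gW
      acc[[i]]$gb <- acc[[i]]$gb + g[[i]]$gb
    }
  }
  acc
}

# One momentum-SGD step with L2 weight decay (velocity update
# v <- momentum * v + grad + wd * w; w <- w - lr * v).
.sgdStep <- function(steps, grads, velocity, lr, momentum, weightDecay) {
  for (i in seq_along(steps)) {
    if (is.null(grads[[i]])) next
    s <- steps[[i]]
    vW <- momentum * velocity[[i]]$vW + grads[[i]]$gW + weightDecay * s$W
    vb <- momentum * velocity[[i]]$vb + as.numeric(grads[[i]]$gb) +
      weightDecay * s$b
    steps[[i]]$W <- s$W - lr * vW
    steps[[i]]$b <- s$b - lr * vb
    velocity[[i]]$vW <- vW
    velocity[[i]]$vb <- vb
  }
  list(steps = steps, velocity = velocity)
}

.zeroVelocity <- function(steps) {
  lapply(steps, function(s)
    if (!is.null(s$W)) list(vW = array(0, dim(s$W)), vb = numeric(length(s$b)))
    else NULL)
}
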