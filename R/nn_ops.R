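# Primitive differentiable tensor ops for the segmentation network.
# Tensors are 4-D arrays [H, W, B, C] (batch folded *before* channels so
# that a [H*W*B, C] matrix view is a zero-copy reshape). Convolutions are
# thin wrappers over compiled tap-loop kernels (src/conv_ops.cpp);
# normalization, activations and resampling stay in vectorized R.
# Everything is deterministic, single-threaded CPU code.

pad_hw <- function(x4, p) {
  if (p == 0L) return(x4)
  d <- dim(x4)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x4
  out
}

crop_hw <- function(xp, p, d) {
  if (p == 0L) return(xp)
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
}

# Standard convolution; W: [k*k*Cin, Cout] with rows blocked per kernel
# tap (tap = ki + k*kj, kernel-row fastest) and channel within tap;
# b: [Cout]. "same" padding for odd k. Kernels are compiled (src/).
conv_fwd <- function(x4, W, b, k, stride) {
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x4, p)
  y <- .conv_fwd_cpp(xp, W, b, k, stride)
  list(y = y, cache = list(xp = xp, dimx = dim(x4), p = p, k = k, stride = stride))
}

conv_bwd <- function(dy, W, cache) {
  r <- .conv_bwd_cpp(cache$xp, dy, W, cache$k, cache$stride)
  list(dx = crop_hw(r$dxp, cache$p, cache$dimx), dW = r$dW, db = r$db)
}

# Depthwise convolution; W: [k*k, C], b: [C].
dwconv_fwd <- function(x4, W, b, k, stride) {
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x4, p)
  y <- .dwconv_fwd_cpp(xp, W, b, k, stride)
  list(y = y, cache = list(xp = xp, dimx = dim(x4), p = p, k = k, stride = stride))
}

dwconv_bwd <- function(dy, W, cache) {
  r <- .dwconv_bwd_cpp(cache$xp, dy, W, cache$k, cache$stride)
  list(dx = crop_hw(r$dxp, cache$p, cache$dimx), dW = r$dW, db = r$db)
}

# Batch normalization over (H, W, B) per channel; channel is the last,
# slowest-varying dimension, so per-channel reductions and broadcasts are
# plain column operations on the [H*W*B, C] view.
bn_fwd <- function(x4, gamma, beta, eps = 1e-5, train = TRUE, stats = NULL) {
  d <- dim(x4); C <- d[4]; n <- d[1] * d[2] * d[3]
  if (train || is.null(stats)) {
    xm <- x4; dim(xm) <- c(n, C)
    mu <- .colSums(xm, n, C) / n
    va <- .colSums(xm * xm, n, C) / n - mu^2
  } else {
    mu <- stats$mean; va <- stats$var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- (x4 - rep(mu, each = n)) * rep(inv_sd, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, dimx = d),
       batch_stats = list(mean = mu, var = va))
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$dimx; C <- d[4]; n <- d[1] * d[2] * d[3]
  xhat <- cache$xhat
  colsum_c <- function(z) { dim(z) <- c(n, C); .colSums(z, n, C) }
  dgamma <- colsum_c(dy * xhat)
  dbeta <- colsum_c(dy)
  dx <- (dy - rep(dbeta / n, each = n) - xhat * rep(dgamma / n, each = n)) *
    rep(gamma * cache$inv_sd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x4) list(y = pmax(x4, 0), cache = x4 > 0)
relu_bwd <- function(dy, cache) dy * cache

sigmoid_fwd <- function(x4) {
  y <- 1 / (1 + exp(-x4))
  list(y = y, cache = y)
}
sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

upsample2_fwd <- function(x4) {
  d <- dim(x4)
  y <- x4[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  list(y = y, cache = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- cache
  o1 <- seq(1L, 2L * d[1], by = 2L); o2 <- seq(1L, 2L * d[2], by = 2L)
  dy[o1, o2, , , drop = FALSE] + dy[o1 + 1L, o2, , , drop = FALSE] +
    dy[o1, o2 + 1L, , , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , , drop = FALSE]
}
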