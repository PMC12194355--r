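# Building blocks of the autoencoder. Every *_forward returns
# list(out, cache) and has a matching *_backward returning list(gx, grads),
# with `grads` structurally identical to the block's parameter list.
#
# Feature maps are dense arrays [H, W, C, N] (height, width, channels, batch).

as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  stopifnot(length(dim(x)) == 4L)
  storage.mode(x) <- "double"
  x
}

conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  cpp_conv2d(x, w, b, as.integer(stride), as.integer(pad))
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

channel_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- Group Normalization ------------------------------------------------
# Fused with the following ReLU in C++ (cpp_gn_relu_fwd / cpp_gn_relu_bw);
# caches keep the normalized activations and inverse standard deviations.

gn_relu_fwd <- function(x, gamma, beta, groups, relu = TRUE, eps = 1e-5) {
  stopifnot(dim(x)[3] %% groups == 0)
  r <- cpp_gn_relu_fwd(x, gamma, beta, as.integer(groups), eps, relu)
  list(out = r$out,
       cache = list(xhat = r$xhat, ivar = r$ivar, gamma = gamma,
                    beta = beta, groups = groups, relu = relu))
}

gn_relu_bwd <- function(gy, cache) {
  r <- cpp_gn_relu_bw(gy, cache$xhat, cache$ivar, cache$gamma, cache$beta,
                      as.integer(cache$groups), cache$relu)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# ---- Multi-scale feature block -----------------------------------------

#' Multi-scale feature block (parallel 3x3 / 5x5 convolutions)
#'
#' Applies two parallel same-padded convolutions with 3x3 and 5x5 kernels
#' (each producing half of the output channels), concatenates them along the
#' channel axis, fuses with a 1x1 convolution, and finishes with Group
#' Normalization and ReLU. Spatial size is preserved.
#'
#' @param x feature map array `[H, W, C, N]` (a plain matrix is treated as
#'   a single-channel, single-image map).
#' @param params parameter sublist as created by [init_ecae()].
#' @param gn_groups number of Group Normalization groups.
#' @return `list(out, cache)`; `out` is the `[H, W, C_out, N]` feature map.
#' @export
msfb_forward <- function(x, params, gn_groups = 8L) {
  x <- as_feature_map(x)
  y3 <- conv2d(x, params$w3, params$b3, 1L, 1L)
  y5 <- conv2d(x, params$w5, params$b5, 1L, 2L)
  cat <- channel_concat(y3, y5)
  f <- conv2d(cat, params$wf, params$bf, 1L, 0L)
  gn <- gn_relu_fwd(f, params$gn_gamma, params$gn_beta, gn_groups)
  list(out = gn$out,
       cache = list(x = x, cat = cat, gn = gn$cache, c3 = dim(y3)[3]))
}

msfb_backward <- function(params, cache, gy) {
  gnb <- gn_relu_bwd(gy, cache$gn)
  fb <- cpp_conv2d_bw(cache$cat, params$wf, gnb$dx, 1L, 0L)
  c3 <- cache$c3
  d3 <- fb$dx[, , seq_len(c3), , drop = FALSE]
  d5 <- fb$dx[, , -seq_len(c3), , drop = FALSE]
  b3 <- cpp_conv2d_bw(cache$x, params$w3, d3, 1L, 1L)
  b5 <- cpp_conv2d_bw(cache$x, params$w5, d5, 1L, 2L)
  list(gx = b3$dx + b5$dx,
       grads = list(w3 = b3$dw, b3 = b3$db, w5 = b5$dw, b5 = b5$db,
                    wf = fb$dw, bf = fb$db,
                    gn_gamma = gnb$dgamma, gn_beta = gnb$dbeta))
}

# ---- Channel attention (squeeze-and-excitation style) -------------------

#' Channel attention gate
#'
#' Computes a per-channel descriptor by global average pooling, passes it
#' through a bottlenecked fully connected pathway (`C -> C/r -> C`) with ReLU
#' and sigmoid activations, and rescales each channel of the input by the
#' resulting gate in (0, 1).
#'
#' @inheritParams msfb_forward
#' @return `list(out, cache)`; `cache$gate` holds the `[C, N]` gate matrix.
#' @export
channel_attention_forward <- function(x, params) {
  x <- as_feature_map(x)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (ncol(params$W1) != C || C %% nrow(params$W1) != 0) {
    stop(sprintf(
      "channel_attention: %d channels not compatible with reduction pathway %d -> %d",
      C, ncol(params$W1), nrow(params$W1)))
  }
  xm <- x
  dim(xm) <- c(H * W, C * N)
  s <- .colMeans(xm, H * W, C * N)
  dim(s) <- c(C, N)
  z1 <- params$W1 %*% s + params$b1
  mask1 <- z1 > 0
  a1 <- z1 * mask1
  z2 <- params$W2 %*% a1 + params$b2
  gate <- sigmoid(z2)
  list(out = cpp_channel_scale(x, gate),
       cache = list(x = x, s = s, a1 = a1, mask1 = mask1, gate = gate,
                    dims = d))
}

channel_attention_backward <- function(params, cache, gy) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gx <- cpp_channel_scale(gy, cache$gate)
  prod <- gy * cache$x
  dim(prod) <- c(H * W, C * N)
  dgate <- .colSums(prod, H * W, C * N)
  dim(dgate) <- c(C, N)
  dz2 <- dgate * cache$gate * (1 - cache$gate)
  dW2 <- dz2 %*% t(cache$a1)
  db2 <- rowSums(dz2)
  dz1 <- (t(params$W2) %*% dz2) * cache$mask1
  dW1 <- dz1 %*% t(cache$s)
  db1 <- rowSums(dz1)
  ds <- t(params$W1) %*% dz1
  dsf <- rep(ds / (H * W), each = H * W)
  dim(dsf) <- d
  list(gx = gx + dsf,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- Strided-convolution downsampling -----------------------------------

#' Strided-convolution downsampling
#'
#' 3x3 convolution with stride 2 (padding 1) halving both spatial dimensions,
#' followed by Group Normalization and ReLU. Requires even spatial dimensions.
#'
#' @inheritParams msfb_forward
#' @return `list(out, cache)`.
#' @export
downsample_forward <- function(x, params, gn_groups = 8L) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop(sprintf("downsample: spatial dims (%d x %d) must be even", d[1], d[2]))
  }
  y <- conv2d(x, params$w, params$b, 2L, 1L)
  gn <- gn_relu_fwd(y, params$gn_gamma, params$gn_beta, gn_groups)
  list(out = gn$out, cache = list(x = x, gn = gn$cache))
}

downsample_backward <- function(params, cache, gy) {
  gnb <- gn_relu_bwd(gy, cache$gn)
  cb <- cpp_conv2d_bw(cache$x, params$w, gnb$dx, 2L, 1L)
  list(gx = cb$dx,
       grads = list(w = cb$dw, b = cb$db,
                    gn_gamma = gnb$dgamma, gn_beta = gnb$dbeta))
}

# ---- 1x1 bottleneck ------------------------------------------------------

#' 1x1 convolutional bottleneck
#'
#' Per-pixel linear map (1x1 convolution) halving the channel count,
#' followed by ReLU. Spatial size is preserved.
#'
#' @inheritParams msfb_forward
#' @return `list(out, cache)`.
#' @export
bottleneck_forward <- function(x, params) {
  x <- as_feature_map(x)
  if (dim(x)[3] < 2) stop("bottleneck: needs at least 2 input channels")
  y <- conv2d(x, params$w, params$b, 1L, 0L)
  r <- relu_fwd(y)
  list(out = r$out, cache = list(x = x, mask = r$mask))
}

bottleneck_backward <- function(params, cache, gy) {
  g <- gy * cache$mask
  cb <- cpp_conv2d_bw(cache$x, params$w, g, 1L, 0L)
  list(gx = cb$dx, grads = list(w = cb$dw, b = cb$db))
}

# ---- Efficient residual block -------------------------------------------

#' Efficient residual block (depthwise separable convolution + skip)
#'
#' Depthwise 3x3 convolution, pointwise 1x1 convolution, Group Normalization
#' and ReLU, added to the input through an identity skip connection. With
#' all-zero convolution weights the block is the identity map.
#'
#' @inheritParams msfb_forward
#' @return `list(out, cache)`.
#' @export
erb_forward <- function(x, params, gn_groups = 8L) {
  x <- as_feature_map(x)
  dwo <- cpp_dwconv2d(x, params$wd, 1L)
  pw <- conv2d(dwo, params$wp, params$bp, 1L, 0L)
  gn <- gn_relu_fwd(pw, params$gn_gamma, params$gn_beta, gn_groups)
  list(out = x + gn$out,
       cache = list(x = x, dwo = dwo, gn = gn$cache))
}

erb_backward <- function(params, cache, gy) {
  gnb <- gn_relu_bwd(gy, cache$gn)
  pb <- cpp_conv2d_bw(cache$dwo, params$wp, gnb$dx, 1L, 0L)
  db <- cpp_dwconv2d_bw(cache$x, params$wd, pb$dx, 1L)
  list(gx = gy + db$dx,
       grads = list(wd = db$dw, wp = pb$dw, bp = pb$db,
                    gn_gamma = gnb$dgamma, gn_beta = gnb$dbeta))
}

# ---- Transposed-convolution upsampling ----------------------------------

#' Transposed-convolution upsampling
#'
#' Transposed convolution with kernel 4, stride 2 and padding 1 (exactly
#' doubling both spatial dimensions), followed by Group Normalization and
#' ReLU. The kernel/stride/padding combination makes the doubling exact and
#' avoids checkerboard artifacts.
#'
#' @inheritParams msfb_forward
#' @return `list(out, cache)`.
#' @export
upsample_forward <- function(x, params, gn_groups = 8L) {
  x <- as_feature_map(x)
  y <- cpp_tconv2d(x, params$w, params$b, 2L, 1L)
  gn <- gn_relu_fwd(y, params$gn_gamma, params$gn_beta, gn_groups)
  list(out = gn$out, cache = list(x = x, gn = gn$cache))
}

upsample_backward <- function(params, cache, gy) {
  gnb <- gn_relu_bwd(gy, cache$gn)
  tb <- cpp_tconv2d_bw(cache$x, params$w, gnb$dx, 2L, 1L)
  list(gx = tb$dx,
       grads = list(w = tb$dw, b = tb$db,
                    gn_gamma = gnb$dgamma, gn_beta = gnb$dbeta))
}
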