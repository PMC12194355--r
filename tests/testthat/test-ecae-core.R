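# Architecture blocks against brute-force sliding-window oracles, shape
# contracts and the parameter inventory.

test_that("same-padded and strided convolutions match the sliding-window oracle", {
  x <- with_seed(1L, array(rnorm(8 * 8 * 3), c(8, 8, 3, 1)))
  w <- with_seed(2L, array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)))
  b <- with_seed(3L, rnorm(4))
  fast <- scintiden:::conv2d(x, w, b, 1L, 1L)
  expect_lt(max(abs(fast[, , , 1] - slow_conv2d(x[, , , 1], w, b, 1, 1))),
            1e-6)
  fast2 <- scintiden:::conv2d(x, w, b, 2L, 1L)
  expect_lt(max(abs(fast2[, , , 1] - slow_conv2d(x[, , , 1], w, b, 2, 1))),
            1e-6)
  w5 <- with_seed(4L, array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2)))
  fast5 <- scintiden:::conv2d(x, w5, numeric(2), 1L, 2L)
  expect_lt(max(abs(fast5[, , , 1] -
                    slow_conv2d(x[, , , 1], w5, numeric(2), 1, 2))), 1e-6)
})

test_that("stride-2 convolution equals dense convolution then row/column subsampling", {
  x <- with_seed(5L, array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))
  w <- with_seed(6L, array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2)))
  dense <- slow_conv2d(x[, , , 1], w, numeric(2), 1, 1)
  sub <- dense[seq(1, 8, by = 2), seq(1, 8, by = 2), , drop = FALSE]
  fast <- scintiden:::conv2d(x, w, numeric(2), 2L, 1L)
  expect_lt(max(abs(fast[, , , 1] - sub)), 1e-6)
})

test_that("depthwise convolution matches the per-channel oracle", {
  x <- with_seed(7L, array(rnorm(6 * 6 * 2), c(6, 6, 2, 1)))
  w <- with_seed(8L, array(rnorm(3 * 3 * 2), c(3, 3, 2)))
  fast <- scintiden:::cpp_dwconv2d(x, w, 1L)
  expect_lt(max(abs(fast[, , , 1] - slow_dwconv2d(x[, , , 1], w, 1))), 1e-6)
})

test_that("the transposed convolution is the exact adjoint of the strided convolution", {
  x <- with_seed(9L, array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))
  w <- with_seed(10L, array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3)))
  y <- scintiden:::cpp_conv2d(x, w, numeric(3), 2L, 1L)
  u <- with_seed(11L, array(rnorm(length(y)), dim(y)))
  tx <- scintiden:::cpp_tconv2d(u, w, numeric(2), 2L, 1L)
  expect_lt(abs(sum(y * u) - sum(x * tx)), 1e-6)
})

test_that("group normalization matches a literal per-group oracle", {
  x <- with_seed(12L, array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2)))
  gamma <- with_seed(13L, runif(4, 0.5, 1.5))
  beta <- with_seed(14L, rnorm(4, 0, 0.1))
  fast <- scintiden:::gn_relu_fwd(x, gamma, beta, groups = 2L, relu = FALSE)
  expect_lt(max(abs(fast$out - slow_group_norm(x, gamma, beta, 2L))), 1e-6)
})

msfb_params <- function(cin, w, seed = 1L) {
  with_seed(seed, list(
    w3 = array(rnorm(3 * 3 * cin * (w / 2)), c(3, 3, cin, w / 2)),
    b3 = rnorm(w / 2),
    w5 = array(rnorm(5 * 5 * cin * (w / 2)), c(5, 5, cin, w / 2)),
    b5 = rnorm(w / 2),
    wf = array(rnorm(w * w), c(1, 1, w, w)), bf = rnorm(w),
    gn_gamma = runif(w, 0.5, 1.5), gn_beta = rnorm(w, 0, 0.1)))
}

test_that("the multi-scale block composes conv, fusion, GN and ReLU as specified", {
  p <- msfb_params(2L, 4L)
  x <- with_seed(20L, array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))
  got <- msfb_forward(x, p, gn_groups = 2L)
  expect_identical(dim(got$out)[1:2], c(8L, 8L))   # same padding

  y3 <- slow_conv2d(x[, , , 1], p$w3, p$b3, 1, 1)
  y5 <- slow_conv2d(x[, , , 1], p$w5, p$b5, 1, 2)
  cat4 <- array(c(y3, y5), c(8, 8, 4, 1))
  fused <- slow_conv2d(cat4[, , , 1], p$wf, p$bf, 1, 0)
  gn <- slow_group_norm(array(fused, c(8, 8, 4, 1)), p$gn_gamma, p$gn_beta, 2L)
  expect_lt(max(abs(got$out - pmax(gn, 0))), 1e-6)

  zero <- lapply(p, function(a) a * 0)
  got0 <- msfb_forward(x, zero, gn_groups = 2L)
  expect_true(all(got0$out == 0))                  # all-zero weights, post-ReLU
})

test_that("attention gates are in (0,1), 0.5 for zero input, and diagonal weights decouple channels", {
  p <- with_seed(21L, list(W1 = matrix(rnorm(4 * 8), 4, 8), b1 = rnorm(4),
                           W2 = matrix(rnorm(8 * 4), 8, 4), b2 = rnorm(8)))
  x <- with_seed(22L, array(rnorm(6 * 6 * 8), c(6, 6, 8, 1)))
  got <- channel_attention_forward(x, p)
  expect_true(all(got$cache$gate > 0 & got$cache$gate < 1))

  z <- array(0, c(6, 6, 8, 1))
  pz <- list(W1 = matrix(1, 4, 8), b1 = numeric(4),
             W2 = matrix(1, 8, 4), b2 = numeric(8))
  gz <- channel_attention_forward(z, pz)
  expect_equal(as.vector(gz$cache$gate), rep(0.5, 8))
  expect_true(all(gz$out == 0))

  # 2-channel hand oracle with diagonal FC weights (reduction r = 1)
  pd <- list(W1 = diag(c(2, 3)), b1 = numeric(2),
             W2 = diag(c(0.5, -1)), b2 = numeric(2))
  x2 <- array(0, c(4, 4, 2, 1))
  x2[, , 1, 1] <- 1; x2[, , 2, 1] <- 2
  g1 <- channel_attention_forward(x2, pd)$cache$gate
  # hand computation: s = (1, 2); z1 = (2, 6); a1 = (2, 6);
  # z2 = (1, -6); gate = sigmoid(z2)
  expect_equal(as.vector(g1), c(1 / (1 + exp(-1)), 1 / (1 + exp(6))),
               tolerance = 1e-12)
  x2b <- x2; x2b[, , 1, 1] <- 5                  # scale channel 1 only
  g2 <- channel_attention_forward(x2b, pd)$cache$gate
  expect_equal(g2[2, 1], g1[2, 1], tolerance = 1e-12)

  expect_error(channel_attention_forward(array(0, c(4, 4, 6, 1)), pd),
               "not compatible")
})

test_that("downsampling halves spatial dims and rejects odd inputs", {
  p <- with_seed(23L, list(w = array(rnorm(3 * 3 * 4 * 4), c(3, 3, 4, 4)),
                           b = rnorm(4), gn_gamma = rep(1, 4),
                           gn_beta = numeric(4)))
  x <- with_seed(24L, array(rnorm(64 * 64 * 4), c(64, 64, 4, 1)))
  got <- downsample_forward(x, p, gn_groups = 2L)
  expect_identical(dim(got$out)[1:2], c(32L, 32L))
  expect_error(downsample_forward(array(0, c(7, 8, 4, 1)), p, 2L), "even")

  zero <- list(w = p$w * 0, b = numeric(4), gn_gamma = rep(1, 4),
               gn_beta = numeric(4))
  expect_true(all(downsample_forward(x, zero, 2L)$out == 0))
})

test_that("the 1x1 bottleneck is a per-pixel linear map", {
  W <- matrix(c(1, 2, -1, 0.5, 0, 3), nrow = 2, byrow = TRUE) # 2x3
  p <- list(w = array(t(W), c(1, 1, 3, 2)), b = c(0.1, -0.2))
  x <- with_seed(25L, array(rnorm(2 * 2 * 3), c(2, 2, 3, 1)))
  got <- bottleneck_forward(x, p)
  expect_identical(dim(got$out)[1:2], c(2L, 2L))
  for (i in 1:2) for (j in 1:2) {
    expected <- pmax(W %*% x[i, j, , 1] + p$b, 0)
    expect_equal(as.vector(got$out[i, j, , 1]), as.vector(expected),
                 tolerance = 1e-12)
  }
  # identity sub-block on nonnegative input passes channels through
  pid <- list(w = array(c(1, 0, 0, 0, 0, 1, 0, 0), c(1, 1, 4, 2)),
              b = numeric(2))
  xp <- abs(with_seed(26L, array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))))
  gid <- bottleneck_forward(xp, pid)
  expect_equal(gid$out[, , 1, 1], xp[, , 1, 1], tolerance = 1e-12)
  expect_equal(gid$out[, , 2, 1], xp[, , 2, 1], tolerance = 1e-12)
  expect_error(bottleneck_forward(array(0, c(2, 2, 1, 1)), p), "2 input")
})

test_that("the efficient residual block is the identity at zero weights and matches the dense oracle", {
  C <- 2L
  p <- with_seed(27L, list(wd = array(rnorm(3 * 3 * C), c(3, 3, C)),
                           wp = array(rnorm(C * C), c(1, 1, C, C)),
                           bp = rnorm(C),
                           gn_gamma = runif(C, 0.5, 1.5),
                           gn_beta = rnorm(C, 0, 0.1)))
  x <- with_seed(28L, array(rnorm(6 * 6 * C), c(6, 6, C, 1)))
  got <- erb_forward(x, p, gn_groups = 1L)
  expect_identical(dim(got$out), dim(x))

  dw <- slow_dwconv2d(x[, , , 1], p$wd, 1)
  pw <- slow_conv2d(dw, p$wp, p$bp, 1, 0)
  gn <- slow_group_norm(array(pw, c(6, 6, C, 1)), p$gn_gamma, p$gn_beta, 1L)
  expect_lt(max(abs(got$out - (x + pmax(gn, 0)))), 1e-6)

  zero <- list(wd = p$wd * 0, wp = p$wp * 0, bp = numeric(C),
               gn_gamma = rep(1, C), gn_beta = numeric(C))
  expect_equal(erb_forward(x, zero, 1L)$out, x, tolerance = 1e-12)
})

test_that("upsampling exactly doubles spatial dimensions", {
  p <- with_seed(29L, list(w = array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3)),
                           b = rnorm(2), gn_gamma = rep(1, 2),
                           gn_beta = numeric(2)))
  x <- with_seed(30L, array(rnorm(32 * 32 * 3), c(32, 32, 3, 1)))
  got <- upsample_forward(x, p, gn_groups = 1L)
  expect_identical(dim(got$out)[1:2], c(64L, 64L))
  zero <- list(w = p$w * 0, b = numeric(2), gn_gamma = rep(1, 2),
               gn_beta = numeric(2))
  expect_true(all(upsample_forward(x, zero, 1L)$out == 0))
})

test_that("the full model preserves shape, stays in [0,1], and is deterministic", {
  cfg <- tiny_model_config(init_seed = 31L)
  params <- init_ecae(cfg)
  x <- rand_img(64, 64, 32L)
  y <- ecae_forward(params, cfg, x)
  expect_identical(dim(y), c(64L, 64L))
  expect_true(all(y >= 0 & y <= 1))
  expect_identical(ecae_forward(params, cfg, x), y)

  x2 <- rand_img(32, 32, 33L)
  expect_identical(dim(ecae_forward(params, cfg, x2)), c(32L, 32L))
  expect_error(ecae_forward(params, cfg, rand_img(30, 30, 34L)),
               "divisible by 4")
})

test_that("model configuration validates widths and kernel policy", {
  expect_error(model_config(encoder_widths = c(12L, 64L), gn_groups = 8L),
               "gn_groups")
  expect_error(model_config(encoder_widths = c(32L, 36L), gn_groups = 4L,
                            attention_reduction = 8L),
               "attention_reduction")
  cfg <- model_config()
  expect_identical(cfg$msfb_kernels, c(3L, 5L))
  expect_identical(cfg$decoder_widths, c(64L, 32L))
})

test_that("the parameter inventory equals a layer-by-layer hand tally and grows with width", {
  cfg <- model_config(init_seed = 1L)
  p <- init_ecae(cfg)
  # hand tally, default config: widths (32, 64), r = 8, decoder (64, 32)
  msfb <- function(cin, w) {
    (3 * 3 * cin * w / 2 + w / 2) + (5 * 5 * cin * w / 2 + w / 2) +
      (w * w + w) + 2 * w
  }
  attn <- function(w, r) (w / r) * w + w / r + w * (w / r) + w
  down <- function(w) 3 * 3 * w * w + w + 2 * w
  up <- function(cin, d) 4 * 4 * d * cin + d + 2 * d
  erb <- function(d) 3 * 3 * d + d * d + d + 2 * d
  tally <- msfb(1, 32) + attn(32, 8) + down(32) +
    msfb(32, 64) + attn(64, 8) + down(64) +
    (64 * 32 + 32) +                                   # bottleneck 64 -> 32
    up(32, 64) + erb(64) + up(64, 32) + erb(32) +
    (3 * 3 * 32 * 1 + 1)                               # final conv
  expect_identical(count_parameters(p), as.integer(tally))

  p2 <- init_ecae(model_config(encoder_widths = c(64L, 128L)))
  expect_gt(count_parameters(p2), count_parameters(p))
  expect_identical(count_parameters(init_ecae(cfg)), count_parameters(p))
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- tiny_model_config(init_seed = 44L)
  p <- init_ecae(cfg)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_checkpoint(f, p, cfg, seeds = list(init = 44L))
  ck <- load_checkpoint(f)
  expect_identical(ck$params, p)
  expect_identical(ck$config, cfg)
  x <- rand_img(32, 32, 45L)
  expect_identical(ecae_forward(ck$params, ck$config, x),
                   ecae_forward(p, cfg, x))
  expect_error(load_checkpoint("nope.rds"), "not found")
})
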