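# Independent brute-force oracles. These deliberately share no code with the
# package implementation: convolutions are direct sliding-window loops, SSIM
# is a literal per-window evaluation of its defining formula.

# Direct sliding-window cross-correlation; x [H,W,Cin], w [kh,kw,Cin,Cout].
slow_conv2d <- function(x, w, b, stride = 1, pad = 0) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  out <- array(0, c(Ho, Wo, Co))
  for (co in seq_len(Co)) {
    for (oi in seq_len(Ho)) {
      for (oj in seq_len(Wo)) {
        ii <- (oi - 1) * stride; jj <- (oj - 1) * stride
        out[oi, oj, co] <- sum(xp[ii + seq_len(kh), jj + seq_len(kw), ,
                                  drop = FALSE] *
                               as.vector(w[, , , co])) + b[co]
      }
    }
  }
  out
}

# Per-channel (depthwise) direct convolution; w [kh,kw,C].
slow_dwconv2d <- function(x, w, pad = 1) {
  C <- dim(x)[3]
  out <- array(0, dim(x))
  for (c in seq_len(C)) {
    wc <- array(w[, , c], c(dim(w)[1], dim(w)[2], 1, 1))
    xc <- array(x[, , c], c(dim(x)[1], dim(x)[2], 1))
    out[, , c] <- slow_conv2d(xc, wc, 0, stride = 1, pad = pad)[, , 1]
  }
  out
}

# Literal group normalization over (H, W, channels-in-group) per sample.
slow_group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); C <- d[3]; cg <- C %/% groups
  out <- array(0, d)
  for (n in seq_len(d[4])) {
    for (g in seq_len(groups)) {
      ch <- (g - 1) * cg + seq_len(cg)
      block <- x[, , ch, n, drop = FALSE]
      mu <- mean(block); va <- mean((block - mu)^2)
      for (k in seq_len(cg)) {
        c_idx <- ch[k]
        out[, , c_idx, n] <- gamma[c_idx] *
          (x[, , c_idx, n] - mu) / sqrt(va + eps) + beta[c_idx]
      }
    }
  }
  out
}

# Literal mean Gaussian-window SSIM: loops over every valid window position
# and evaluates the defining formula on the window's weighted statistics.
slow_ssim <- function(x, y, data_range = 1, win = 11, sigma = 1.5,
                      K1 = 0.01, K2 = 0.03) {
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  r <- (win - 1) / 2
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  wmat <- outer(g1, g1)
  H <- nrow(x); W <- ncol(x)
  vals <- numeric((H - win + 1) * (W - win + 1))
  k <- 0
  for (i in seq_len(H - win + 1)) {
    for (j in seq_len(W - win + 1)) {
      xb <- x[i:(i + win - 1), j:(j + win - 1)]
      yb <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(wmat * xb); my <- sum(wmat * yb)
      vx <- sum(wmat * xb^2) - mx^2
      vy <- sum(wmat * yb^2) - my^2
      cxy <- sum(wmat * xb * yb) - mx * my
      k <- k + 1
      vals[k] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  }
  mean(vals)
}

# Small model configuration used by training / pipeline tests.
tiny_model_config <- function(init_seed = 1L) {
  model_config(encoder_widths = c(8L, 16L), gn_groups = 4L,
               attention_reduction = 4L, init_seed = init_seed)
}

rand_img <- function(H, W, seed) {
  with_seed(seed, matrix(runif(H * W), H, W))
}

# In-memory dose pairs from the phantom simulator (max-normalized, like
# build_pairs does for on-disk data).
synthetic_pairs_mem <- function(n_subjects, fraction = 0.3, H = 32L,
                                region = "pelvis", base_seed = 1L,
                                background_rate = 10, bone_rate_scale = 5) {
  pairs <- list()
  for (s in seq_len(n_subjects)) {
    spec <- phantom_spec(region, c(H, H), background_rate = background_rate,
                         bone_rate_scale = bone_rate_scale,
                         subject_seed = derive_seed(base_seed, s))
    map <- generate_activity_map(spec)
    full <- acquire_counts(map, 1.0, seed = derive_seed(base_seed, s, 2L),
                           subject_id = sprintf("s%03d", s))
    low <- thin_counts(full, fraction, seed = derive_seed(base_seed, s, 3L))
    normv <- function(cts) {
      v <- cts / max(max(cts), 1)
      normalized_image(v)
    }
    pairs[[s]] <- structure(
      list(low = normv(low$counts), full = normv(full$counts),
           subject_id = sprintf("s%03d", s), region = region,
           view = "anterior", dose_fraction = fraction,
           id = sprintf("s%03d_%s_anterior_%03.0f", s, region,
                        100 * fraction)),
      class = "dose_pair")
  }
  pairs
}

# Flatten a parameter tree to a named numeric vector and write it back;
# used by finite-difference checks.
flatten_params <- function(tree) {
  unlist(rapply(unclass(tree), as.vector, how = "unlist"))
}

unflatten_params <- function(tree, vec) {
  i <- 0
  walk <- function(a) {
    if (is.list(a)) return(lapply(a, walk))
    out <- a
    out[] <- vec[i + seq_len(length(a))]
    i <<- i + length(a)
    out
  }
  res <- walk(unclass(tree))
  class(res) <- class(tree)
  res
}
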