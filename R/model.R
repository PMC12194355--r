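#' Architectural configuration of the convolutional autoencoder
#'
#' The encoder is `n_downsamples` stages of (multi-scale feature block ->
#' channel attention -> strided downsampling); a 1x1 bottleneck halves the
#' channel count; the decoder mirrors with (transposed-convolution upsampling
#' -> efficient residual blocks); a final 3x3 convolution produces the
#' single-channel denoised image, mapped to `[0, 1]` by the output activation.
#'
#' @param encoder_widths channel count after each encoder stage. Every width
#'   must be divisible by `gn_groups` and by `attention_reduction` (and hence
#'   even, as each multi-scale branch carries half of the channels).
#' @param attention_reduction reduction ratio `r` of the channel-attention
#'   bottleneck (`C -> C/r -> C`).
#' @param gn_groups number of Group Normalization groups.
#' @param erb_per_stage efficient residual blocks per decoder stage.
#' @param decoder_widths channel counts of the decoder stages; default is the
#'   encoder widths mirrored (reversed), which gives the decoder enough
#'   capacity to reconstruct fine structure through the bottleneck.
#' @param output_activation `"sigmoid"` (default, guarantees outputs in
#'   `[0, 1]`) or `"clamp"` (plain final convolution clipped to `[0, 1]`).
#' @param init_seed integer seed for weight initialization.
#' @return an object of class `"ecae_config"`.
#' @export
model_config <- function(encoder_widths = c(32L, 64L),
                         attention_reduction = 8L,
                         gn_groups = 8L,
                         erb_per_stage = 1L,
                         decoder_widths = NULL,
                         output_activation = c("sigmoid", "clamp"),
                         init_seed = 1L) {
  output_activation <- match.arg(output_activation)
  encoder_widths <- as.integer(encoder_widths)
  if (length(encoder_widths) < 1) stop("need at least one encoder stage")
  if (any(encoder_widths %% gn_groups != 0)) {
    stop("every encoder width must be divisible by gn_groups")
  }
  if (any(encoder_widths %% attention_reduction != 0)) {
    stop("every encoder width must be divisible by attention_reduction")
  }
  if (is.null(decoder_widths)) {
    decoder_widths <- rev(encoder_widths)
  }
  decoder_widths <- as.integer(decoder_widths)
  if (length(decoder_widths) != length(encoder_widths)) {
    stop("decoder_widths must have one entry per encoder stage")
  }
  if (any(decoder_widths %% gn_groups != 0)) {
    stop("every decoder width must be divisible by gn_groups")
  }
  structure(list(
    encoder_widths = encoder_widths,
    n_downsamples = length(encoder_widths),
    attention_reduction = as.integer(attention_reduction),
    gn_groups = as.integer(gn_groups),
    erb_per_stage = as.integer(erb_per_stage),
    msfb_kernels = c(3L, 5L),        # larger kernels deliberately excluded
    final_kernel = 3L,
    decoder_widths = decoder_widths,
    output_activation = output_activation,
    init_seed = as.integer(init_seed)
  ), class = "ecae_config")
}

# Kaiming-uniform fan-in initialization for a ReLU network.
kaiming_array <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}


#' Initialize autoencoder parameters
#'
#' Creates every learnable weight of the model described by a
#' [model_config()]: multi-scale branch kernels, attention FC pairs, strided
#' downsampling kernels, the 1x1 bottleneck, depthwise/pointwise decoder
#' kernels, transposed-convolution kernels, the final 3x3 kernel, and the
#' Group Normalization affine terms. Deterministic given
#' `config$init_seed`.
#'
#' @param config an `"ecae_config"` object.
#' @param in_channels number of input image channels (1 for grayscale).
#' @return nested named list of numeric arrays (class `"ecae_params"`).
#' @export
init_ecae <- function(config, in_channels = 1L) {
  stopifnot(inherits(config, "ecae_config"))
  with_seed(config$init_seed, {
    r <- config$attention_reduction
    enc <- list()
    cin <- as.integer(in_channels)
    for (i in seq_len(config$n_downsamples)) {
      w <- config$encoder_widths[i]
      half <- w %/% 2L
      enc[[i]] <- list(
        msfb = list(
          w3 = kaiming_array(c(3, 3, cin, half), 9 * cin),
          b3 = numeric(half),
          w5 = kaiming_array(c(5, 5, cin, half), 25 * cin),
          b5 = numeric(half),
          wf = kaiming_array(c(1, 1, w, w), w),
          bf = numeric(w),
          gn_gamma = rep(1, w), gn_beta = numeric(w)
        ),
        attn = list(
          W1 = kaiming_array(c(w %/% r, w), w),
          b1 = numeric(w %/% r),
          W2 = kaiming_array(c(w, w %/% r), w %/% r),
          b2 = numeric(w)
        ),
        down = list(
          w = kaiming_array(c(3, 3, w, w), 9 * w),
          b = numeric(w),
          gn_gamma = rep(1, w), gn_beta = numeric(w)
        )
      )
      cin <- w
    }
    wlast <- config$encoder_widths[config$n_downsamples]
    cb <- wlast %/% 2L
    bottleneck <- list(
      w = kaiming_array(c(1, 1, wlast, cb), wlast),
      b = numeric(cb)
    )
    dec <- list()
    cin <- cb
    for (j in seq_len(config$n_downsamples)) {
      dj <- config$decoder_widths[j]
      erbs <- lapply(seq_len(config$erb_per_stage), function(k) {
        list(
          wd = kaiming_array(c(3, 3, dj), 9),
          wp = kaiming_array(c(1, 1, dj, dj), dj),
          bp = numeric(dj),
          gn_gamma = rep(1, dj), gn_beta = numeric(dj)
        )
      })
      dec[[j]] <- list(
        up = list(
          # conv-layout [kh, kw, Cout, Cin] for the adjoint formulation
          w = kaiming_array(c(4, 4, dj, cin), 16 * cin),
          b = numeric(dj),
          gn_gamma = rep(1, dj), gn_beta = numeric(dj)
        ),
        erbs = erbs
      )
      cin <- dj
    }
    final <- list(
      w = kaiming_array(c(3, 3, cin, in_channels), 9 * cin),
      b = numeric(in_channels)
    )
    structure(list(enc = enc, bottleneck = bottleneck, dec = dec,
                   final = final),
              class = "ecae_params")
  })
}

#' Count scalar learnable parameters
#'
#' @param params an `"ecae_params"` object (or any nested list of arrays).
#' @return integer number of scalar learnables.
#' @export
count_parameters <- function(params) {
  sum(rapply(unclass(params), length, how = "unlist"))
}

#' Forward pass of the autoencoder
#'
#' Runs encoder (multi-scale feature block, channel attention, strided
#' downsampling per stage), 1x1 bottleneck, decoder (transposed-convolution
#' upsampling and efficient residual blocks per stage) and the final 3x3
#' convolution with the configured output activation. Fully convolutional:
#' any input whose spatial dimensions are divisible by
#' `2^config$n_downsamples` is mapped to an output of identical size in
#' `[0, 1]`. Deterministic given `params`.
#'
#' @param params model parameters from [init_ecae()] or a trained checkpoint.
#' @param config the matching `"ecae_config"`.
#' @param x input image(s): an `[H, W]` matrix in `[0, 1]`, or an
#'   `[H, W, 1, N]` array for a batch.
#' @param want_cache keep intermediate activations for backpropagation.
#' @return if `want_cache` is FALSE, the output array shaped like `x`;
#'   otherwise `list(out, cache)`.
#' @export
ecae_forward <- function(params, config, x, want_cache = FALSE) {
  was_matrix <- is.matrix(x)
  x <- as_feature_map(x)
  d <- dim(x)
  div <- 2L^config$n_downsamples
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("input dims %d x %d must be divisible by %d",
                 d[1], d[2], div))
  }
  g <- config$gn_groups
  caches <- list(enc = list(), dec = list())
  h <- x
  for (i in seq_len(config$n_downsamples)) {
    m <- msfb_forward(h, params$enc[[i]]$msfb, g)
    a <- channel_attention_forward(m$out, params$enc[[i]]$attn)
    dn <- downsample_forward(a$out, params$enc[[i]]$down, g)
    h <- dn$out
    if (want_cache) caches$enc[[i]] <- list(msfb = m$cache, attn = a$cache,
                                            down = dn$cache)
  }
  bo <- bottleneck_forward(h, params$bottleneck)
  h <- bo$out
  if (want_cache) caches$bottleneck <- bo$cache
  for (j in seq_len(config$n_downsamples)) {
    up <- upsample_forward(h, params$dec[[j]]$up, g)
    h <- up$out
    ec <- list()
    for (k in seq_along(params$dec[[j]]$erbs)) {
      e <- erb_forward(h, params$dec[[j]]$erbs[[k]], g)
      h <- e$out
      if (want_cache) ec[[k]] <- e$cache
    }
    if (want_cache) caches$dec[[j]] <- list(up = up$cache, erbs = ec)
  }
  z <- conv2d(h, params$final$w, params$final$b, 1L, 1L)
  if (config$output_activation == "sigmoid") {
    out <- sigmoid(z)
    if (want_cache) caches$final <- list(x = h, out = out, act = "sigmoid")
  } else {
    out <- pmin(pmax(z, 0), 1)
    dim(out) <- dim(z)
    if (want_cache) caches$final <- list(x = h, z = z, act = "clamp")
  }
  if (want_cache) return(list(out = out, cache = caches))
  if (was_matrix) dim(out) <- d[1:2]
  out
}

# Backpropagate dL/d(output) through the whole model.
ecae_backward <- function(params, config, cache, gout) {
  g <- config$gn_groups
  fin <- cache$final
  if (fin$act == "sigmoid") {
    gz <- gout * fin$out * (1 - fin$out)
  } else {
    pass <- (fin$z > 0 & fin$z < 1) | (fin$z <= 0 & gout < 0) |
      (fin$z >= 1 & gout > 0)
    gz <- gout * pass
  }
  fb <- cpp_conv2d_bw(fin$x, params$final$w, gz, 1L, 1L)
  gh <- fb$dx
  grads <- list(final = list(w = fb$dw, b = fb$db))
  grads$dec <- vector("list", config$n_downsamples)
  for (j in rev(seq_len(config$n_downsamples))) {
    erbs <- params$dec[[j]]$erbs
    ge <- vector("list", length(erbs))
    for (k in rev(seq_along(erbs))) {
      eb <- erb_backward(erbs[[k]], cache$dec[[j]]$erbs[[k]], gh)
      gh <- eb$gx
      ge[[k]] <- eb$grads
    }
    ub <- upsample_backward(params$dec[[j]]$up, cache$dec[[j]]$up, gh)
    gh <- ub$gx
    grads$dec[[j]] <- list(up = ub$grads, erbs = ge)
  }
  bb <- bottleneck_backward(params$bottleneck, cache$bottleneck, gh)
  gh <- bb$gx
  grads$bottleneck <- bb$grads
  grads$enc <- vector("list", config$n_downsamples)
  for (i in rev(seq_len(config$n_downsamples))) {
    db <- downsample_backward(params$enc[[i]]$down, cache$enc[[i]]$down, gh)
    ab <- channel_attention_backward(params$enc[[i]]$attn,
                                     cache$enc[[i]]$attn, db$gx)
    mb <- msfb_backward(params$enc[[i]]$msfb, cache$enc[[i]]$msfb, ab$gx)
    gh <- mb$gx
    grads$enc[[i]] <- list(msfb = mb$grads, attn = ab$grads, down = db$grads)
  }
  # reorder to match params structure
  grads[c("enc", "bottleneck", "dec", "final")]
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the architecture configuration, all parameter arrays
#' and the seeds needed to reproduce inference; a version field guards the
#' format.
#'
#' @param path file path (`.rds`).
#' @param params,config model parameters and configuration.
#' @param history optional training history.
#' @param seeds optional named list of seeds used.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint list.
#' @export
save_checkpoint <- function(path, params, config, history = NULL,
                            seeds = list()) {
  obj <- list(version = "scintiden-checkpoint-1",
              config = config, params = params,
              history = history, seeds = seeds)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$version, "scintiden-checkpoint-1")) {
    stop("unrecognized checkpoint version")
  }
  obj
}
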