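# Mini-batch Adam training of the autoencoder with early stopping.

#' Training configuration
#'
#' Defaults follow the study protocol: hybrid-loss weight `lambda = 0.7`,
#' Adam with learning rate 1e-3, batch size 16, at most 2000 mini-batch
#' updates, early stopping with patience 50 validation evaluations (one
#' evaluation per update by default). Adam moment parameters use the
#' standard values `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`.
#'
#' @param loss_lambda hybrid-loss weighting factor in `[0, 1]`.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_iterations maximum number of mini-batch updates.
#' @param patience number of consecutive non-improving validation
#'   evaluations after which training halts.
#' @param validate_every evaluate the validation loss every this many
#'   updates.
#' @param val_max_pairs optional cap on the number of validation pairs used
#'   per evaluation (a fixed seed-chosen subset); `NULL` uses all.
#' @param seed integer seed governing batching and subsampling.
#' @return a `"training_config"` list.
#' @export
training_config <- function(loss_lambda = 0.7, learning_rate = 1e-3,
                            batch_size = 16L, max_iterations = 2000L,
                            patience = 50L, validate_every = 1L,
                            val_max_pairs = NULL, seed = 1L) {
  if (loss_lambda < 0 || loss_lambda > 1) stop("loss_lambda must be in [0, 1]")
  if (patience < 1) stop("patience must be >= 1")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (validate_every < 1) stop("validate_every must be >= 1")
  structure(list(loss_lambda = loss_lambda, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience),
                 validate_every = as.integer(validate_every),
                 val_max_pairs = val_max_pairs,
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 seed = as.integer(seed)),
            class = "training_config")
}

# Stack the low / full images of pairs into [H, W, 1, N] arrays.
stack_pairs <- function(pairs) {
  lows <- lapply(pairs, function(p) p$low$values)
  fulls <- lapply(pairs, function(p) p$full$values)
  d <- dim(lows[[1]])
  X <- array(unlist(lows), c(d[1], d[2], 1L, length(pairs)))
  Tg <- array(unlist(fulls), c(d[1], d[2], 1L, length(pairs)))
  list(X = X, target = Tg)
}

adam_init <- function(params) {
  list(m = tree_map(function(a) a * 0, params),
       v = tree_map(function(a) a * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  lr <- cfg$learning_rate
  upd <- tree_map2(function(m, v) {
    lr * (m / corr1) / (sqrt(v / corr2) + cfg$eps)
  }, state$m, state$v)
  params_new <- tree_map2(function(p, u) p - u, unclass(params), upd)
  class(params_new) <- class(params)
  list(params = params_new, state = state)
}

# Mean hybrid loss over a stacked set of images (no gradients).
mean_loss_stack <- function(params, model_config, X, Tg, lambda, mcfg) {
  out <- ecae_forward(params, model_config, X)
  n <- dim(X)[4]
  tot <- 0
  for (i in seq_len(n)) {
    tot <- tot + hybrid_loss(out[, , 1, i], Tg[, , 1, i], lambda, mcfg)$total
  }
  tot / n
}

#' Train the autoencoder
#'
#' Iterates mini-batch Adam updates on the hybrid MSE + SSIM loss. Batches
#' are drawn epoch-wise: each epoch the training pairs are reshuffled under
#' a per-epoch derived seed and the remainder modulo the batch size is
#' randomly excluded (see [make_batches()]). A baseline validation
#' evaluation at iteration 0 establishes the best loss; thereafter the
#' validation loss is evaluated every `validate_every` updates and training
#' halts when `max_iterations` is reached or `patience` consecutive
#' evaluations fail to improve on the best. The parameters achieving the
#' best validation loss are returned (not the last iterate). Reproducible
#' given the seeds.
#'
#' @param params initial parameters from [init_ecae()].
#' @param model_config the `"ecae_config"`.
#' @param train_pairs,val_pairs lists of `"dose_pair"` objects (both
#'   non-empty).
#' @param config a [training_config()].
#' @param verbose print a progress line per validation evaluation.
#' @return list with `params` (best), `history` (data.frame: iteration,
#'   train_total, train_mse, train_ssim_term, val_loss, patience_counter),
#'   `stop_reason` (`"max_iterations"` or `"early_stop"`),
#'   `best_iteration`, `best_val_loss`, `final_params`.
#' @export
train_ecae <- function(params, model_config, train_pairs, val_pairs,
                       config = training_config(), verbose = FALSE) {
  if (length(train_pairs) == 0) stop("train_pairs must be non-empty")
  if (length(val_pairs) == 0) {
    stop("validation set is empty but early stopping (finite patience) ",
         "needs one; provide val_pairs")
  }
  mcfg <- metric_config(data_range = 1.0)
  tr <- stack_pairs(train_pairs)
  va <- stack_pairs(val_pairs)
  if (!is.null(config$val_max_pairs) &&
      dim(va$X)[4] > config$val_max_pairs) {
    keep <- with_seed(derive_seed(config$seed, 999L),
                      sample.int(dim(va$X)[4], config$val_max_pairs))
    va$X <- va$X[, , , keep, drop = FALSE]
    va$target <- va$target[, , , keep, drop = FALSE]
  }
  n_train <- dim(tr$X)[4]
  lambda <- config$loss_lambda

  val_loss <- function(p) {
    mean_loss_stack(p, model_config, va$X, va$target, lambda, mcfg)
  }

  best_val <- val_loss(params)        # baseline at iteration 0
  best_params <- params
  best_iter <- 0L
  patience_counter <- 0L
  state <- adam_init(params)
  hist <- vector("list", config$max_iterations)
  stop_reason <- "max_iterations"

  epoch <- 0L
  queue <- list()
  it <- 0L
  while (it < config$max_iterations) {
    if (length(queue) == 0) {
      epoch <- epoch + 1L
      queue <- make_batches(seq_len(n_train),
                            batch_size = min(config$batch_size, n_train),
                            seed = derive_seed(config$seed, epoch),
                            quiet = TRUE)
      attr(queue, "dropped") <- NULL
    }
    it <- it + 1L
    idx <- queue[[1]]
    queue <- queue[-1]

    Xb <- tr$X[, , , idx, drop = FALSE]
    Tb <- tr$target[, , , idx, drop = FALSE]
    fw <- ecae_forward(params, model_config, Xb, want_cache = TRUE)
    B <- length(idx)
    gout <- array(0, dim(fw$out))
    tot <- 0; mse_t <- 0; ssim_t <- 0
    for (b in seq_len(B)) {
      lb <- hybrid_loss(fw$out[, , 1, b], Tb[, , 1, b], lambda, mcfg)
      tot <- tot + lb$total; mse_t <- mse_t + lb$mse_term
      ssim_t <- ssim_t + lb$ssim_term
      gout[, , 1, b] <- hybrid_loss_grad(fw$out[, , 1, b], Tb[, , 1, b],
                                         lambda, mcfg) / B
    }
    grads <- ecae_backward(params, model_config, fw$cache, gout)
    st <- adam_step(params, grads, state, config)
    params <- st$params; state <- st$state

    vl <- NA_real_
    if (it %% config$validate_every == 0) {
      vl <- val_loss(params)
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_params <- params
        best_iter <- it
        patience_counter <- 0L
      } else {
        patience_counter <- patience_counter + 1L
      }
      if (verbose) {
        message(sprintf(
          "iter %d  train %.5f (mse %.5f, 1-ssim %.5f)  val %.5f  patience %d",
          it, tot / B, mse_t / B, ssim_t / B, vl, patience_counter))
      }
    }
    hist[[it]] <- data.frame(iteration = it, train_total = tot / B,
                             train_mse = mse_t / B,
                             train_ssim_term = ssim_t / B,
                             val_loss = vl,
                             patience_counter = patience_counter)
    if (patience_counter >= config$patience) {
      stop_reason <- "early_stop"
      break
    }
  }
  history <- do.call(rbind, hist[seq_len(it)])
  list(params = best_params, history = history, stop_reason = stop_reason,
       best_iteration = best_iter, best_val_loss = best_val,
       final_params = params)
}

#' Denoise a list of images with a trained model
#'
#' Runs batched forward passes; input order is preserved and the result is
#' invariant to the batch partitioning.
#'
#' @param params trained parameters.
#' @param model_config the matching `"ecae_config"`.
#' @param images list of matrices or `"normalized_image"` objects in
#'   `[0, 1]`.
#' @param batch_size forward-pass batch size.
#' @return list of denoised matrices in `[0, 1]` (empty list for empty
#'   input).
#' @export
denoise_images <- function(params, model_config, images, batch_size = 16L) {
  if (length(images) == 0) return(list())
  mats <- lapply(images, function(im) {
    if (inherits(im, "normalized_image")) im$values else im
  })
  d <- dim(mats[[1]])
  out <- vector("list", length(mats))
  starts <- seq(1, length(mats), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, length(mats))
    X <- array(unlist(mats[idx]), c(d[1], d[2], 1L, length(idx)))
    Y <- ecae_forward(params, model_config, X)
    for (k in seq_along(idx)) out[[idx[k]]] <- Y[, , 1, k]
  }
  out
}
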