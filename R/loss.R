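#' Hybrid MSE + SSIM training loss
#'
#' `L_total = lambda * L_MSE + (1 - lambda) * (1 - SSIM(output, target))`,
#' computed on normalized images in `[0, 1]` (`data_range = 1`). The MSE term
#' rewards pixel-wise fidelity, the SSIM term structural preservation;
#' `lambda` (default 0.7) trades the two off.
#'
#' @param output,target numeric matrices in `[0, 1]` of identical dimensions.
#' @param lambda weighting factor in `[0, 1]`.
#' @param config a [metric_config()] with `data_range = 1` (the SSIM window
#'   settings are shared with [img_ssim()], a single source of truth).
#' @return a `"loss_breakdown"` list with `total`, `mse_term` and
#'   `ssim_term` (`1 - SSIM`, in `[0, 2]`); `total` equals
#'   `lambda * mse_term + (1 - lambda) * ssim_term` exactly.
#' @export
hybrid_loss <- function(output, target, lambda = 0.7,
                        config = metric_config(data_range = 1.0)) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (!identical(dim(output), dim(target))) {
    stop(sprintf("shape mismatch: output %s vs target %s",
                 paste(dim(output), collapse = "x"),
                 paste(dim(target), collapse = "x")))
  }
  mse_term <- img_mse(output, target)
  ssim_term <- 1 - img_ssim(output, target, config)
  structure(list(total = lambda * mse_term + (1 - lambda) * ssim_term,
                 mse_term = mse_term, ssim_term = ssim_term,
                 lambda = lambda),
            class = "loss_breakdown")
}

#' Gradient of the hybrid loss with respect to the output image
#'
#' Analytic gradient: `lambda * 2 * (output - target) / N` for the MSE term
#' plus `(1 - lambda)` times the negated Gaussian-window SSIM gradient.
#'
#' @inheritParams hybrid_loss
#' @return a matrix shaped like `output`.
#' @export
hybrid_loss_grad <- function(output, target, lambda = 0.7,
                             config = metric_config(data_range = 1.0)) {
  N <- length(output)
  g <- lambda * 2 * (output - target) / N
  if (lambda < 1) {
    g <- g - (1 - lambda) * ssim_grad(output, target, config)
  }
  g
}
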