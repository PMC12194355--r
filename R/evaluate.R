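# Quantitative evaluation: per-pair PSNR/SSIM records and per-dose
# summaries with paired t-tests.

#' Evaluate dose pairs with and without denoising
#'
#' For every pair computes PSNR and SSIM of the low-dose image against the
#' full-dose reference ("original") and of the denoised low-dose image
#' against the same reference ("denoised"). Metrics are computed on the
#' stored 8-bit scale by default (`data_range = 255`): normalized `[0, 1]`
#' values are multiplied by 255 first.
#'
#' @param params,model_config trained model (ignored when
#'   `identity_denoiser = TRUE`).
#' @param pairs non-empty list of `"dose_pair"` objects.
#' @param config a [metric_config()]; default 8-bit scale.
#' @param identity_denoiser debug flag: use the identity map as the
#'   denoiser, so original and denoised columns coincide.
#' @param batch_size forward-pass batch size.
#' @return data.frame with one row per pair: `id`, `subject_id`, `region`,
#'   `view`, `dose_fraction`, `psnr_original`, `psnr_denoised`,
#'   `ssim_original`, `ssim_denoised`.
#' @export
evaluate_pairs <- function(params, model_config, pairs,
                           config = metric_config(data_range = 255),
                           identity_denoiser = FALSE, batch_size = 16L) {
  if (length(pairs) == 0) stop("test set is empty")
  lows <- lapply(pairs, function(p) p$low$values)
  if (identity_denoiser) {
    den <- lows
  } else {
    if (is.null(params)) stop("no trained parameters supplied")
    den <- denoise_images(params, model_config, lows, batch_size)
  }
  scale <- config$data_range
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    lo <- p$low$values * scale
    fu <- p$full$values * scale
    de <- den[[i]] * scale
    data.frame(id = p$id, subject_id = p$subject_id, region = p$region,
               view = p$view, dose_fraction = p$dose_fraction,
               psnr_original = img_psnr(lo, fu, config),
               psnr_denoised = img_psnr(de, fu, config),
               ssim_original = img_ssim(lo, fu, config),
               ssim_denoised = img_ssim(de, fu, config),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize metric records by dose level
#'
#' Groups per-pair records by `dose_fraction` (ascending) and reports mean
#' SSIM and PSNR for the original and denoised comparisons together with
#' paired t-test p-values (original vs denoised, per metric). Groups with
#' fewer than two pairs, or zero-variance differences, report `NA`
#' p-values. Infinite PSNR values (identical images) are excluded from the
#' means with a warning.
#'
#' @param records data.frame from [evaluate_pairs()].
#' @return data.frame with one row per dose fraction: `dose_fraction`, `n`,
#'   `ssim_original`, `ssim_denoised`, `p_ssim`, `psnr_original`,
#'   `psnr_denoised`, `p_psnr`.
#' @export
summarize_by_dose <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("records must be non-empty")
  fr <- sort(unique(records$dose_fraction))
  if (any(!is.finite(records$psnr_original)) ||
      any(!is.finite(records$psnr_denoised))) {
    warning("infinite PSNR (identical images) excluded from means")
  }
  fin_mean <- function(x) mean(x[is.finite(x)])
  rows <- lapply(fr, function(f) {
    g <- records[records$dose_fraction == f, ]
    p_ssim <- p_psnr <- NA_real_
    if (nrow(g) >= 2) {
      p_ssim <- paired_t_test(g$ssim_denoised, g$ssim_original)$p_value
      ok <- is.finite(g$psnr_denoised) & is.finite(g$psnr_original)
      if (sum(ok) >= 2) {
        p_psnr <- paired_t_test(g$psnr_denoised[ok], g$psnr_original[ok])$p_value
      }
    }
    data.frame(dose_fraction = f, n = nrow(g),
               ssim_original = fin_mean(g$ssim_original),
               ssim_denoised = fin_mean(g$ssim_denoised),
               p_ssim = p_ssim,
               psnr_original = fin_mean(g$psnr_original),
               psnr_denoised = fin_mean(g$psnr_denoised),
               p_psnr = p_psnr)
  })
  do.call(rbind, rows)
}
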