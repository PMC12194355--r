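#' Image-quality metric configuration
#'
#' @param data_range dynamic range `I_max` of the images: 255 for stored
#'   8-bit comparisons, 1 for normalized images.
#' @param ssim_window odd Gaussian window size for SSIM (default 11).
#' @param ssim_sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 SSIM stability constants; `C1 = (K1*I_max)^2`,
#'   `C2 = (K2*I_max)^2` keep the luminance and contrast terms away from
#'   division by zero.
#' @return a `"metric_config"` list with `C1`, `C2` precomputed.
#' @export
metric_config <- function(data_range = 1.0, ssim_window = 11L,
                          ssim_sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  ssim_window <- as.integer(ssim_window)
  if (ssim_window %% 2 != 1 || ssim_window < 3) {
    stop("ssim_window must be an odd integer >= 3")
  }
  if (data_range <= 0) stop("data_range must be positive")
  structure(list(data_range = data_range, ssim_window = ssim_window,
                 ssim_sigma = ssim_sigma, K1 = K1, K2 = K2,
                 C1 = (K1 * data_range)^2, C2 = (K2 * data_range)^2),
            class = "metric_config")
}

#' Mean squared error between two images
#'
#' @param x,y numeric matrices of identical dimensions.
#' @return mean of squared pixel differences.
#' @export
img_mse <- function(x, y) {
  if (!identical(dim(x), dim(y))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x")))
  }
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 10 * log10(I_max^2 / MSE)`. For identical images (`MSE = 0`) the
#' sentinel `Inf` is returned; aggregation routines exclude it with a
#' warning.
#'
#' @param x,y numeric matrices of identical dimensions.
#' @param config a [metric_config()]; its `data_range` is `I_max`.
#' @return PSNR in decibels, or `Inf` when `x == y`.
#' @export
img_psnr <- function(x, y, config = metric_config()) {
  m <- img_mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(config$data_range^2 / m)
}

# Normalized 1-d Gaussian window.
gaussian_window <- function(n, sigma) {
  r <- (n - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g / sum(g)
}

# Banded matrices performing 'valid' separable correlation:
# filtered = A %*% X %*% B.
valid_filter_mats <- function(H, W, g) {
  n <- length(g)
  A <- matrix(0, H - n + 1, H)
  for (i in seq_len(H - n + 1)) A[i, i:(i + n - 1)] <- g
  B <- matrix(0, W, W - n + 1)
  for (j in seq_len(W - n + 1)) B[j:(j + n - 1), j] <- g
  list(A = A, B = B)
}

# Local windowed statistics shared by the SSIM metric and the SSIM loss term.
ssim_stats <- function(x, y, config) {
  if (!identical(dim(x), dim(y))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x")))
  }
  n <- config$ssim_window
  if (nrow(x) < n || ncol(x) < n) {
    stop(sprintf(
      "image %d x %d smaller than the SSIM window (%d); use a smaller window",
      nrow(x), ncol(x), n))
  }
  g <- gaussian_window(n, config$ssim_sigma)
  fm <- valid_filter_mats(nrow(x), ncol(x), g)
  f <- function(z) fm$A %*% z %*% fm$B
  mu_x <- f(x); mu_y <- f(y)
  sxx <- f(x * x) - mu_x^2
  syy <- f(y * y) - mu_y^2
  sxy <- f(x * y) - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + config$C1
  A2 <- 2 * sxy + config$C2
  B1 <- mu_x^2 + mu_y^2 + config$C1
  B2 <- sxx + syy + config$C2
  list(mu_x = mu_x, mu_y = mu_y, var_x = sxx, var_y = syy, cov_xy = sxy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, map = (A1 * A2) / (B1 * B2),
       fm = fm)
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM with local statistics taken over a Gaussian window (default
#' 11 x 11, sigma 1.5, the convention of the standard SSIM literature),
#' computed in 'valid' mode (the half-window border is excluded, matching the
#' original reference implementation). Symmetric in its two arguments and
#' bounded above by 1.
#'
#' @param x,y numeric matrices of identical dimensions, at the scale implied
#'   by `config$data_range`.
#' @param config a [metric_config()].
#' @param components also return the local mean / variance / covariance maps.
#' @return mean SSIM, or `list(ssim, components)` when `components = TRUE`.
#' @export
img_ssim <- function(x, y, config = metric_config(), components = FALSE) {
  st <- ssim_stats(x, y, config)
  val <- mean(st$map)
  if (!components) return(val)
  list(ssim = val,
       components = st[c("mu_x", "mu_y", "var_x", "var_y", "cov_xy", "map")])
}

# Gradient of mean SSIM(x, y) with respect to x.
ssim_grad <- function(x, y, config, st = NULL) {
  if (is.null(st)) st <- ssim_stats(x, y, config)
  M <- length(st$map)
  d_mu  <- 2 * st$A2 * (st$mu_y * st$B1 - st$mu_x * st$A1) / (st$B1^2 * st$B2)
  d_var <- -st$A1 * st$A2 / (st$B1 * st$B2^2)
  d_cov <- 2 * st$A1 / (st$B1 * st$B2)
  A <- st$fm$A; B <- st$fm$B
  back <- function(z) t(A) %*% z %*% t(B)   # adjoint of the valid filter
  grad <- back(d_mu - 2 * st$mu_x * d_var - st$mu_y * d_cov) +
    2 * x * back(d_var) + y * back(d_cov)
  grad / M
}
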