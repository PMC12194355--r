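# MSE/PSNR/SSIM metric fidelity, per-dose summaries and the paired
# statistical procedures.

m255 <- metric_config(data_range = 255)
m1 <- metric_config(data_range = 1)

test_that("MSE matches hand arithmetic", {
  x <- matrix(0, 2, 2)
  y <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(img_mse(x, x), 0)
  expect_equal(img_mse(x, y), 7.5)                 # (1+4+9+16)/4
  expect_equal(img_mse(x + 3, x), 9)               # constant difference d^2
  expect_error(img_mse(x, matrix(0, 3, 3)), "shape mismatch")
})

test_that("PSNR follows its defining formula with the infinity sentinel", {
  a <- matrix(0, 8, 8); b <- matrix(255, 8, 8)
  expect_equal(img_psnr(a, b, m255), 0)            # MSE = I_max^2
  expect_identical(img_psnr(a, a, m255), Inf)      # identical images
  c1 <- matrix(0, 8, 8); c2 <- matrix(1, 8, 8)
  expect_equal(img_psnr(c1, c2, m255), 48.1308, tolerance = 1e-4)
  expect_equal(img_psnr(c1, c2, m255), 10 * log10(255^2), tolerance = 1e-10)
})

test_that("PSNR is strictly decreasing in MSE", {
  base <- matrix(128, 16, 16)
  psnrs <- vapply(c(1, 2, 5, 10, 25), function(d) {
    img_psnr(base + d, base, m255)
  }, numeric(1))
  expect_true(all(diff(psnrs) < 0))
})

test_that("SSIM handles identity, constants, symmetry and bounds", {
  x <- rand_img(32, 32, 1L)
  expect_lt(abs(img_ssim(x, x, m1) - 1), 1e-9)

  c1 <- matrix(0.3, 32, 32); c2 <- matrix(0.7, 32, 32)
  closed <- (2 * 0.3 * 0.7 + m1$C1) / (0.3^2 + 0.7^2 + m1$C1)
  expect_equal(img_ssim(c1, c2, m1), closed, tolerance = 1e-12)

  y <- rand_img(32, 32, 2L)
  expect_equal(img_ssim(x, y, m1), img_ssim(y, x, m1), tolerance = 1e-12)
  expect_lte(img_ssim(x, y, m1), 1)
  expect_error(img_ssim(matrix(0, 8, 8), matrix(0, 8, 8), m1),
               "smaller than the SSIM window")

  comp <- img_ssim(x, y, m1, components = TRUE)
  expect_true(all(comp$components$var_x >= -1e-12))
  expect_true(all(abs(comp$components$cov_xy) <=
                  sqrt(pmax(comp$components$var_x, 0) *
                       pmax(comp$components$var_y, 0)) + 1e-9))
})

test_that("SSIM agrees with the literal windowed-formula oracle and a frozen external reference", {
  for (s in 1:3) {
    x <- rand_img(32, 32, 200L + s)
    y <- pmin(pmax(x + 0.1 * rand_img(32, 32, 300L + s) - 0.05, 0), 1)
    expect_lt(abs(img_ssim(x, y, m1) - slow_ssim(x, y, 1)), 1e-6)
  }
  # deterministic analytic pair, value frozen from scikit-image's
  # structural_similarity (gaussian_weights, sigma 1.5, win 11,
  # population covariance, data_range 1)
  r <- matrix(rep(seq_len(64), 64) / 64, 64, 64)
  cc <- t(r)
  xs <- 0.5 + 0.5 * sin(6 * r + 4 * cc)
  ys <- pmin(pmax(xs + 0.2 * cos(9 * r - 3 * cc), 0), 1)
  expect_equal(img_ssim(xs, ys, m1), 0.6590035701, tolerance = 1e-6)
})

test_that("evaluate_pairs records both comparisons for every pair", {
  pairs <- synthetic_pairs_mem(4L, fraction = 0.4, H = 32L, base_seed = 7L)
  cfg <- tiny_model_config(init_seed = 3L)
  p <- init_ecae(cfg)
  rec <- evaluate_pairs(p, cfg, pairs, m255)
  expect_identical(nrow(rec), 4L)
  expect_true(all(rec$ssim_original <= 1 & rec$ssim_denoised <= 1))
  expect_true(all(is.finite(rec$psnr_original)))

  idr <- evaluate_pairs(NULL, NULL, pairs, m255, identity_denoiser = TRUE)
  expect_equal(idr$psnr_denoised, idr$psnr_original, tolerance = 1e-12)
  expect_equal(idr$ssim_denoised, idr$ssim_original, tolerance = 1e-12)

  expect_error(evaluate_pairs(p, cfg, list(), m255), "empty")
})

test_that("per-dose summaries aggregate with hand-computed means and t-tests", {
  rec <- data.frame(
    id = sprintf("p%d", 1:6),
    subject_id = "s1", region = "pelvis", view = "anterior",
    dose_fraction = rep(c(0.3, 0.5), each = 3),
    psnr_original = c(20, 21, 22, 25, 26, 27),
    psnr_denoised = c(23, 24, 26, 26, 27, 29),
    ssim_original = c(0.80, 0.82, 0.84, 0.90, 0.91, 0.92),
    ssim_denoised = c(0.88, 0.89, 0.91, 0.91, 0.92, 0.94))
  s <- summarize_by_dose(rec)
  expect_identical(nrow(s), 2L)
  expect_identical(s$dose_fraction, c(0.3, 0.5))
  expect_equal(s$ssim_original[1], mean(c(0.80, 0.82, 0.84)))
  expect_equal(s$psnr_denoised[2], mean(c(26, 27, 29)))
  expect_equal(s$p_ssim[1],
               paired_t_test(c(0.88, 0.89, 0.91),
                             c(0.80, 0.82, 0.84))$p_value)

  # identical records within a group: mean passes through, p not computable
  rec2 <- rec[rec$dose_fraction == 0.3, ]
  rec2$ssim_denoised <- rec2$ssim_original
  rec2$psnr_denoised <- rec2$psnr_original
  s2 <- summarize_by_dose(rec2)
  expect_true(is.na(s2$p_ssim))
  expect_equal(s2$ssim_denoised, s2$ssim_original)
})

test_that("seven protocol fractions yield seven summary rows", {
  fr <- protocol_fractions(low_only = TRUE)
  rec <- do.call(rbind, lapply(seq_along(fr), function(i) {
    data.frame(id = sprintf("p%d", i * 2 + 0:1), subject_id = "s1",
               region = "pelvis", view = "anterior", dose_fraction = fr[i],
               psnr_original = c(20, 21) + i, psnr_denoised = c(22, 23) + i,
               ssim_original = 0.8 + 0.01 * i + c(0, 0.002),
               ssim_denoised = 0.85 + 0.01 * i + c(0, 0.002))
  }))
  s <- summarize_by_dose(rec)
  expect_identical(nrow(s), 7L)
  expect_identical(s$dose_fraction, fr)
})

test_that("infinite PSNR is excluded from means with a warning", {
  rec <- data.frame(id = c("a", "b"), subject_id = "s1", region = "pelvis",
                    view = "anterior", dose_fraction = 0.3,
                    psnr_original = c(30, 32), psnr_denoised = c(Inf, 40),
                    ssim_original = c(0.9, 0.91),
                    ssim_denoised = c(1.0, 0.95))
  expect_warning(s <- summarize_by_dose(rec), "infinite PSNR")
  expect_equal(s$psnr_denoised, 40)
})

test_that("paired t-test duplicates the textbook statistic", {
  a <- with_seed(21L, rnorm(30, mean = 1))
  b <- with_seed(22L, rnorm(30))
  res <- paired_t_test(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(30))
  p_manual <- 2 * pt(abs(t_manual), df = 29, lower.tail = FALSE)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_identical(res$n, 30L)
  # independent statistics routine agrees
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  # antisymmetry
  expect_equal(paired_t_test(b, a)$statistic, -res$statistic,
               tolerance = 1e-12)

  # strong shift: p below 1e-10
  b2 <- with_seed(23L, rnorm(30, sd = 0.01))
  res2 <- paired_t_test(b2 + 1.0, b2)
  expect_lt(res2$p_value, 1e-10)

  # zero variance marker, not an exception
  res3 <- paired_t_test(a, a)
  expect_true(is.na(res3$p_value))
  expect_match(res3$note, "zero-variance")
  expect_error(paired_t_test(a, a[1:10]), "equal length")
})

test_that("TOST equivalence matches the one-sided t oracle on both sides of the bounds", {
  tost_oracle <- function(d, delta) {
    n <- length(d); se <- sd(d) / sqrt(n)
    p_lo <- pt((mean(d) + delta) / se, df = n - 1, lower.tail = FALSE)
    p_hi <- pt((mean(d) - delta) / se, df = n - 1, lower.tail = TRUE)
    max(p_lo, p_hi)
  }
  b <- numeric(50)
  d0 <- with_seed(31L, rnorm(50, mean = 0, sd = 0.1))
  r0 <- tost_equivalence(d0, b, delta = 1.0)
  expect_equal(r0$p_value, tost_oracle(d0, 1.0), tolerance = 1e-12)
  expect_lt(r0$p_value, 0.001)                 # equivalence within +/- 1
  # independent statistics routine agrees with each one-sided test
  expect_equal(r0$p_lower,
               t.test(d0, mu = -1, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(r0$p_upper,
               t.test(d0, mu = 1, alternative = "less")$p.value,
               tolerance = 1e-12)

  d2 <- with_seed(32L, rnorm(50, mean = 2.0, sd = 0.1))
  r2 <- tost_equivalence(d2, b, delta = 1.0)
  expect_equal(r2$p_value, tost_oracle(d2, 1.0), tolerance = 1e-12)
  expect_gt(r2$p_value, 0.99)                  # mean far outside the bounds

  expect_identical(r0$bounds, c(-1, 1))
  expect_equal(r0$p_value, max(r0$p_lower, r0$p_upper))
  expect_error(tost_equivalence(d0, b, delta = 0), "positive")
})

test_that("SSIM of low-dose images increases with dose on synthetic data", {
  fr <- c(0.3, 0.6, 0.9)
  ss <- vapply(fr, function(f) {
    pairs <- synthetic_pairs_mem(3L, fraction = f, H = 32L, base_seed = 40L)
    mean(vapply(pairs, function(p) {
      img_ssim(p$low$values * 255, p$full$values * 255, m255)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
})
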