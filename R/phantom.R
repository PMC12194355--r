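# Procedural anatomical phantom and Poisson count acquisition.
#
# The activity map is a noise-free per-pixel emission-rate field (expected
# counts per pixel for a full-length acquisition). Count images are Poisson
# draws from it; low-dose images are binomial thinnings of a full-dose
# acquisition, the exact count-level realization of shortening the
# acquisition time.

#' Dose fractions of the shortened-acquisition protocol
#'
#' The acquisition protocol captures images at 30--100% of the standard
#' acquisition time in 10% steps; the low-dose inputs are the 30--90%
#' fractions and the 100% image is the supervised target.
#'
#' @param low_only return only the 0.3--0.9 input fractions.
#' @return numeric vector of dose fractions.
#' @export
protocol_fractions <- function(low_only = FALSE) {
  f <- seq(0.3, 1.0, by = 0.1)
  if (low_only) f[f < 1.0] else f
}

phantom_regions <- c("pelvis", "thorax")

#' Specification of a synthetic phantom subject
#'
#' @param region `"pelvis"` or `"thorax"`.
#' @param image_size integer `(height, width)`; each dimension must be
#'   divisible by `divisor` (2 raised to the number of encoder downsampling
#'   stages of the model the images will feed).
#' @param background_rate mean soft-tissue counts per pixel per full
#'   acquisition (nonnegative).
#' @param bone_rate_scale multiplicative uptake factor of skeletal
#'   structures (>= 1), so bone emits at `background_rate * bone_rate_scale`.
#' @param lesions list of focal hot spots, each
#'   `list(row =, col =, radius =, intensity =)` with `radius > 0`;
#'   a lesion adds a radially decaying excess of about
#'   `intensity * background_rate` counts at its center.
#' @param subject_seed integer seed controlling the per-subject anatomical
#'   jitter (and the auto-generated lesions in [generate_paired_dataset()]).
#' @param divisor required divisor of the image dimensions.
#' @return a `"phantom_spec"` object.
#' @export
phantom_spec <- function(region = c("pelvis", "thorax"),
                         image_size = c(64L, 64L),
                         background_rate = 10,
                         bone_rate_scale = 5,
                         lesions = list(),
                         subject_seed = 1L,
                         divisor = 4L) {
  region <- match.arg(region)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size <= 0)) {
    stop("image_size must be two positive integers")
  }
  if (any(image_size %% divisor != 0)) {
    stop(sprintf("image_size must be divisible by %d", divisor))
  }
  if (background_rate < 0) stop("background_rate must be nonnegative")
  if (bone_rate_scale < 1) stop("bone_rate_scale must be >= 1")
  for (l in lesions) {
    if (is.null(l$radius) || l$radius <= 0) stop("lesion radius must be > 0")
  }
  structure(list(region = region, image_size = image_size,
                 background_rate = background_rate,
                 bone_rate_scale = bone_rate_scale,
                 lesions = lesions,
                 subject_seed = as.integer(subject_seed)),
            class = "phantom_spec")
}

# 'same' separable Gaussian blur (zero padded); used to soften mask edges.
blur_same <- function(X, sigma = 1.5) {
  r <- ceiling(3 * sigma)
  g <- exp(-(-r:r)^2 / (2 * sigma^2)); g <- g / sum(g)
  H <- nrow(X); W <- ncol(X); n <- length(g)
  A <- matrix(0, H, H)
  for (i in seq_len(H)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1 & idx <= H
    A[i, idx[ok]] <- g[ok]
  }
  B <- matrix(0, W, W)
  for (j in seq_len(W)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1 & idx <= W
    B[idx[ok], j] <- g[ok]
  }
  A %*% X %*% B
}

ellipse_mask <- function(H, W, cy, cx, ry, rx) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

ring_mask <- function(H, W, cy, cx, ry, rx, thickness) {
  ellipse_mask(H, W, cy, cx, ry, rx) &
    !ellipse_mask(H, W, cy, cx, pmax(ry - thickness, 0.5),
                  pmax(rx - thickness, 0.5))
}

# Skeletal template in [0, 1]: spine + rib arcs (thorax), iliac wings +
# sacrum (pelvis). Jitter keeps subjects distinct but anatomy recognizable.
bone_template <- function(region, H, W, subject_seed) {
  with_seed(derive_seed(subject_seed, 11L), {
    j <- function(lo, hi) runif(1, lo, hi)
    mask <- matrix(0, H, W)
    cy <- H / 2 * j(0.95, 1.05)
    cx <- W / 2 * j(0.95, 1.05)
    if (region == "thorax") {
      # spine: vertical column with vertebral modulation
      half_w <- W * 0.045 * j(0.9, 1.1)
      rows <- seq_len(H)
      cols <- seq_len(W)
      spine <- outer(rows >= H * 0.08 & rows <= H * 0.92,
                     abs(cols - cx) <= half_w)
      vert <- 0.75 + 0.25 * sin(2 * pi * rows / (H * 0.09 * j(0.9, 1.1)))^2
      mask <- mask + spine * matrix(vert, H, W)
      # rib arcs: nested elliptical rings on both sides
      n_ribs <- 5L
      for (k in seq_len(n_ribs)) {
        ry <- H * (0.10 + 0.015 * k) * j(0.9, 1.1)
        rx <- W * (0.28 + 0.02 * k) * j(0.9, 1.1)
        ccy <- H * (0.12 + 0.15 * k) * j(0.97, 1.03)
        rib <- ring_mask(H, W, ccy, cx, ry, rx, thickness = max(1.2, H / 48))
        # keep only the lateral/lower parts so arcs do not overwrite the spine
        keep <- outer(seq_len(H) > ccy - ry * 0.2, rep(TRUE, W))
        mask <- pmax(mask, 0.8 * rib * keep)
      }
    } else {
      # pelvis: two iliac-wing ellipse rings, sacrum, pubic arc
      ry <- H * 0.22 * j(0.9, 1.1)
      rx <- W * 0.16 * j(0.9, 1.1)
      off <- W * 0.17 * j(0.9, 1.1)
      wingL <- ring_mask(H, W, cy - H * 0.08, cx - off, ry, rx, H / 18)
      wingR <- ring_mask(H, W, cy - H * 0.08, cx + off, ry, rx, H / 18)
      sacrum <- ellipse_mask(H, W, cy - H * 0.02, cx, H * 0.16, W * 0.07)
      pubis <- ring_mask(H, W, cy + H * 0.22, cx, H * 0.12 * j(0.9, 1.1),
                         W * 0.14 * j(0.9, 1.1), H / 20)
      mask <- pmax(mask, wingL, wingR, 0.9 * sacrum, 0.85 * pubis)
    }
    pmin(blur_same(mask, sigma = max(1, H / 64)), 1)
  })
}

#' Generate a noise-free activity map
#'
#' Builds the region-dependent skeletal template (thorax: spine column plus
#' rib arcs; pelvis: iliac-wing ellipses, sacrum and pubic arc) emitting at
#' `background_rate * bone_rate_scale` over a soft-tissue background of
#' `background_rate`, then adds each lesion as a radially decaying
#' (Gaussian-profile) hot spot. The map is smooth (no sampling noise) and
#' deterministic given `spec$subject_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return an `"activity_map"` with nonnegative finite `values`.
#' @export
generate_activity_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  bg <- spec$background_rate
  bone <- bone_template(spec$region, H, W, spec$subject_seed)
  # soft-tissue body outline so the field of view has an object in it
  body <- blur_same(
    ellipse_mask(H, W, H / 2, W / 2, H * 0.47, W * 0.42) * 1.0,
    sigma = max(1, H / 64))
  values <- bg * body + bg * (spec$bone_rate_scale - 1) * bone
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (l in spec$lesions) {
    d2 <- (y - l$row)^2 + (x - l$col)^2
    values <- values + l$intensity * bg * exp(-d2 / (2 * (l$radius / 2)^2))
  }
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(values = values, region = spec$region, spec = spec),
            class = "activity_map")
}

#' Acquire a Poisson count image from an activity map
#'
#' Each pixel is an independent Poisson draw with mean
#' `activity * dose_fraction`, the counting statistics of a gamma-camera
#' acquisition shortened to `dose_fraction` of the standard time.
#'
#' @param map an `"activity_map"`.
#' @param dose_fraction fraction of the standard acquisition time, in (0, 1].
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param view `"anterior"` or `"posterior"` (metadata).
#' @param subject_id subject identifier (metadata).
#' @return a `"count_image"` with integer counts.
#' @export
acquire_counts <- function(map, dose_fraction, seed,
                           view = c("anterior", "posterior"),
                           subject_id = "s1") {
  stopifnot(inherits(map, "activity_map"))
  view <- match.arg(view)
  if (dose_fraction <= 0 || dose_fraction > 1) {
    stop("dose_fraction must lie in (0, 1]")
  }
  v <- map$values
  counts <- with_seed(seed, rpois(length(v), lambda = v * dose_fraction))
  counts <- matrix(counts, nrow(v), ncol(v))
  structure(list(counts = counts, dose_fraction = dose_fraction,
                 region = map$region, view = view, subject_id = subject_id,
                 seed_used = as.integer(seed)),
            class = "count_image")
}

#' Binomial thinning of a full-dose count image
#'
#' Every recorded count is kept independently with probability `fraction`
#' (`Binomial(n = count, p = fraction)` per pixel). This is the exact
#' count-level realization of a shorter acquisition: thinning a Poisson image
#' is again Poisson with proportionally reduced mean, and the thinned image
#' is pixelwise less than or equal to its parent, mirroring a same-session,
#' same-anatomy, shorter-time acquisition with correlated noise.
#'
#' @param full a full-dose `"count_image"` (`dose_fraction == 1`).
#' @param fraction keep-probability in (0, 1].
#' @param seed integer seed.
#' @return a `"count_image"` at `dose_fraction = fraction`.
#' @export
thin_counts <- function(full, fraction, seed) {
  stopifnot(inherits(full, "count_image"))
  if (full$dose_fraction != 1.0) {
    stop("thin_counts expects a full-dose (dose_fraction = 1) parent image")
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  cts <- full$counts
  thinned <- with_seed(seed,
                       rbinom(length(cts), size = as.vector(cts),
                              prob = fraction))
  out <- full
  out$counts <- matrix(thinned, nrow(cts), ncol(cts))
  out$dose_fraction <- fraction
  out$seed_used <- as.integer(seed)
  out
}

#' Point-source linearity experiment
#'
#' Places a Gaussian-blurred point kernel (sigma 2 px, emulating collimator
#' blur) scaled to `total_mean_counts` in an otherwise empty map, acquires a
#' Poisson count image at each dose fraction, and fits observed total counts
#' against fraction by least squares through the origin. A slope close to
#' `total_mean_counts` with R^2 near 1 confirms that shortening the
#' acquisition time reduces counts proportionally.
#'
#' @param total_mean_counts expected total counts at full acquisition (> 0).
#' @param fractions dose fractions in (0, 1] (default: the 30--100% protocol).
#' @param seed integer seed.
#' @param image_size size of the (square) simulation grid.
#' @param kernel_sigma Gaussian kernel standard deviation in pixels.
#' @return list with `table` (fraction, observed_total), `slope`,
#'   `r_squared`, and the `fit` object.
#' @export
simulate_point_source <- function(total_mean_counts,
                                  fractions = protocol_fractions(),
                                  seed = 1L, image_size = 64L,
                                  kernel_sigma = 2) {
  if (total_mean_counts <= 0) stop("total_mean_counts must be > 0")
  if (length(fractions) == 0) stop("fractions must be non-empty")
  if (any(fractions <= 0 | fractions > 1)) {
    stop("all fractions must lie in (0, 1]")
  }
  S <- as.integer(image_size)
  y <- matrix(seq_len(S), S, S)
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  k <- exp(-((y - (S + 1) / 2)^2 + (x - (S + 1) / 2)^2) / (2 * kernel_sigma^2))
  values <- k / sum(k) * total_mean_counts
  spec <- phantom_spec("pelvis", c(S, S), background_rate = 0, divisor = 1L)
  map <- structure(list(values = values, region = "point_source", spec = spec),
                   class = "activity_map")
  totals <- vapply(seq_along(fractions), function(i) {
    ci <- acquire_counts(map, fractions[i], seed = derive_seed(seed, i))
    sum(ci$counts)
  }, numeric(1))
  tab <- data.frame(fraction = fractions, observed_total = totals)
  fit <- lm(observed_total ~ 0 + fraction, data = tab)
  list(table = tab,
       slope = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       fit = fit)
}

#' Generate a paired low/full-dose synthetic dataset on disk
#'
#' For every subject x region x view, acquires one full-dose count image and
#' derives one image per low-dose fraction by binomial thinning of that same
#' full-dose acquisition (same subject, same anatomy, same session; only the
#' effective acquisition time differs). Images are written as 8-bit grayscale
#' PNGs, counts linearly rescaled by a per-pair shared scale
#' (`255 / max(full counts)`) recorded in the manifest, so low-dose images
#' remain count-comparable to their full-dose parent. One manifest row is
#' written per (low, full) pair. Fully reproducible from `base_seed`.
#'
#' Each subject receives 0--2 random focal lesions (position inside the body,
#' radius 2--4 px scaled with image size, intensity 2--4 times background),
#' drawn from the subject seed.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param regions subset of `c("pelvis", "thorax")`.
#' @param fractions low-dose fractions (default 0.3--0.9 by 0.1).
#' @param base_seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param image_size integer `(height, width)`.
#' @param background_rate,bone_rate_scale full-dose count levels, see
#'   [phantom_spec()].
#' @return the manifest `data.frame` (columns `subject_id`, `region`, `view`,
#'   `dose_fraction`, `path_low`, `path_full`, `count_scale`, `seed`),
#'   invisibly; also written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_paired_dataset <- function(n_subjects, regions = phantom_regions,
                                    fractions = protocol_fractions(low_only = TRUE),
                                    base_seed = 1L, out_dir,
                                    image_size = c(64L, 64L),
                                    background_rate = 10,
                                    bone_rate_scale = 5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  regions <- match.arg(regions, phantom_regions, several.ok = TRUE)
  if (any(fractions >= 1 | fractions <= 0)) {
    stop("low-dose fractions must lie in (0, 1)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create out_dir: %s", out_dir))
  views <- c("anterior", "posterior")
  rows <- list()
  H <- image_size[1]; W <- image_size[2]
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%03d", s)
    for (ri in seq_along(regions)) {
      region <- regions[ri]
      subject_seed <- derive_seed(base_seed, s, ri)
      lesions <- with_seed(derive_seed(subject_seed, 5L), {
        n_les <- sample(0:2, 1)
        lapply(seq_len(n_les), function(k) {
          list(row = runif(1, 0.25 * H, 0.75 * H),
               col = runif(1, 0.25 * W, 0.75 * W),
               radius = runif(1, 2, 4) * H / 64,
               intensity = runif(1, 2, 4))
        })
      })
      spec <- phantom_spec(region, image_size,
                           background_rate = background_rate,
                           bone_rate_scale = bone_rate_scale,
                           lesions = lesions, subject_seed = subject_seed)
      map <- generate_activity_map(spec)
      for (vi in seq_along(views)) {
        vmap <- map
        if (views[vi] == "posterior") {
          vmap$values <- vmap$values[, rev(seq_len(ncol(vmap$values)))]
        }
        acq_seed <- derive_seed(base_seed, s, ri, vi)
        full <- acquire_counts(vmap, 1.0, seed = acq_seed,
                               view = views[vi], subject_id = sid)
        mx <- max(full$counts)
        count_scale <- if (mx > 0) 255 / mx else 1
        path_full <- file.path(out_dir, sprintf("%s_%s_%s_100.png",
                                                sid, region, views[vi]))
        write_count_png(full$counts, count_scale, path_full)
        for (f in fractions) {
          thin_seed <- derive_seed(base_seed, s, ri, vi, round(100 * f))
          low <- thin_counts(full, f, seed = thin_seed)
          path_low <- file.path(out_dir, sprintf("%s_%s_%s_%03.0f.png",
                                                 sid, region, views[vi],
                                                 100 * f))
          write_count_png(low$counts, count_scale, path_low)
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sid, region = region, view = views[vi],
            dose_fraction = f, path_low = path_low, path_full = path_full,
            count_scale = count_scale, seed = thin_seed,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Quantize counts to 8-bit with a fixed linear scale and write as PNG.
write_count_png <- function(counts, count_scale, path) {
  v <- round(counts * count_scale)
  v <- pmin(pmax(v, 0), 255) / 255
  png::writePNG(matrix(v, nrow(counts), ncol(counts)), path)
}
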