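# Reading/writing 8-bit grayscale PNGs, dose-pair construction, dataset
# splitting and batching.

#' Construct a normalized image
#'
#' @param values numeric matrix with all values in `[0, 1]` and finite.
#' @param dose_fraction dose fraction metadata.
#' @param source_path optional originating file.
#' @return a `"normalized_image"` object.
#' @export
normalized_image <- function(values, dose_fraction = NA_real_,
                             source_path = NULL) {
  if (!is.matrix(values) || length(values) == 0) {
    stop("values must be a non-empty matrix")
  }
  if (!all(is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("normalized image values must be finite and in [0, 1]")
  }
  structure(list(values = values, dose_fraction = dose_fraction,
                 source_path = source_path),
            class = "normalized_image")
}

#' Read an 8-bit grayscale PNG as a normalized image
#'
#' Pixel values are divided by 255 into `[0, 1]`.
#'
#' @param path path to an 8-bit single-channel PNG.
#' @param dose_fraction optional dose-fraction metadata to attach.
#' @return a `"normalized_image"`.
#' @export
read_grayscale <- function(path, dose_fraction = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) {
    if (dim(v)[3] > 1) {
      stop(sprintf("multi-channel image not supported: %s", path))
    }
    v <- v[, , 1]
  }
  normalized_image(v, dose_fraction = dose_fraction, source_path = path)
}

#' Write a normalized image as an 8-bit grayscale PNG
#'
#' @param img a `"normalized_image"` or a matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grayscale <- function(img, path) {
  v <- if (inherits(img, "normalized_image")) img$values else img
  png::writePNG(round(v * 255) / 255, path)
  invisible(path)
}

pair_id <- function(subject_id, region, view, dose_fraction) {
  sprintf("%s_%s_%s_%03.0f", subject_id, region, view, 100 * dose_fraction)
}

#' Build dose pairs from a dataset manifest
#'
#' Reads one (low-dose input, full-dose target) image pair per manifest row.
#' By default each image is additionally renormalized by its own maximum
#' (`renormalize = "max"`), emulating the standard per-image intensity
#' normalization of clinical preprocessing so that low- and full-dose images
#' share a common brightness scale; `"none"` keeps the raw `[0, 1]` PNG
#' values (which retain the count-proportional brightness difference).
#'
#' @param manifest a manifest `data.frame` (see [generate_paired_dataset()])
#'   or the path of a manifest CSV.
#' @param renormalize `"max"` (default) or `"none"`.
#' @return list of `"dose_pair"` objects (`low`, `full`, `subject_id`,
#'   `region`, `view`, `dose_fraction`, `id`).
#' @export
build_pairs <- function(manifest, renormalize = c("max", "none")) {
  renormalize <- match.arg(renormalize)
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      stop(sprintf("manifest not found: %s", manifest))
    }
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  # Display maximum taken from a lightly smoothed image: the raw maximum of
  # a photon-count image is a noisy extreme statistic, and normalizing by it
  # injects a random brightness factor into every image; the smoothed
  # maximum halves that jitter. Values above it (isolated hot pixels) clip
  # to 1, like display windowing.
  renorm <- function(img) {
    if (renormalize == "max" && max(img$values) > 0) {
      m <- max(blur_same(img$values, sigma = 1))
      img$values <- pmin(img$values / m, 1)
    }
    img
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    for (p in c(row$path_low, row$path_full)) {
      if (!file.exists(p)) {
        stop(sprintf("manifest row %d: missing file %s", i, p))
      }
    }
    low <- renorm(read_grayscale(row$path_low, row$dose_fraction))
    full <- renorm(read_grayscale(row$path_full, 1.0))
    if (!identical(dim(low$values), dim(full$values))) {
      stop(sprintf("manifest row %d: dimension mismatch %s vs %s", i,
                   paste(dim(low$values), collapse = "x"),
                   paste(dim(full$values), collapse = "x")))
    }
    structure(list(low = low, full = full,
                   subject_id = row$subject_id, region = row$region,
                   view = row$view, dose_fraction = row$dose_fraction,
                   id = pair_id(row$subject_id, row$region, row$view,
                                row$dose_fraction)),
              class = "dose_pair")
  })
}

# Largest-remainder apportionment of n items to the given ratios.
apportion <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split dose pairs into training / validation / test sets
#'
#' Random, seed-reproducible partition at the given ratios (default
#' 75/15/10). With `group_by_subject = TRUE` (default) all pairs of a
#' subject land in the same split, preventing leakage of identical anatomy
#' between training and test; with grouping off the split sizes follow the
#' ratios exactly (largest-remainder rounding, within one item).
#'
#' @param pairs list of `"dose_pair"` objects.
#' @param ratios numeric triple summing to 1.
#' @param seed integer seed.
#' @param group_by_subject keep each subject's pairs together.
#' @return a `"split_assignment"`: lists `train`, `validation`, `test` of
#'   pair ids, plus `ratios`, `seed`, `group_by_subject`.
#' @export
split_dataset <- function(pairs, ratios = c(0.75, 0.15, 0.10), seed = 1L,
                          group_by_subject = TRUE) {
  if (length(pairs) == 0) stop("pairs must be non-empty")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three numbers summing to 1")
  }
  ids <- vapply(pairs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("pair ids must be unique")
  n <- length(pairs)
  if (!group_by_subject) {
    sizes <- apportion(n, ratios)
    perm <- with_seed(seed, sample.int(n))
    train <- ids[perm[seq_len(sizes[1])]]
    validation <- ids[perm[sizes[1] + seq_len(sizes[2])]]
    test <- ids[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]]
  } else {
    subj <- vapply(pairs, function(p) p$subject_id, character(1))
    subjects <- unique(subj)
    perm <- with_seed(seed, sample(subjects))
    counts <- table(subj)[perm]
    cum <- cumsum(as.numeric(counts))
    t1 <- ratios[1] * n
    t2 <- (ratios[1] + ratios[2]) * n
    grp <- ifelse(cum <= t1 + 1e-9, 1L, ifelse(cum <= t2 + 1e-9, 2L, 3L))
    # guarantee non-empty train when any ratio demands it
    if (ratios[1] > 0 && !any(grp == 1L)) grp[1] <- 1L
    assign_of <- setNames(grp, perm)
    gsub <- assign_of[subj]
    train <- ids[gsub == 1L]
    validation <- ids[gsub == 2L]
    test <- ids[gsub == 3L]
  }
  structure(list(train = train, validation = validation, test = test,
                 ratios = ratios, seed = as.integer(seed),
                 group_by_subject = group_by_subject),
            class = "split_assignment")
}

#' Persist / restore a split assignment as JSON
#'
#' @param split a `"split_assignment"`.
#' @param path JSON file path.
#' @return `write_split` returns `path` invisibly; `read_split` the
#'   `"split_assignment"`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  if (!file.exists(path)) stop(sprintf("split file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("train", "validation", "test")) {
    obj[[k]] <- as.character(unlist(obj[[k]]))
  }
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "split_assignment")
}

# Select pairs by id, preserving the order of `ids`.
pairs_by_id <- function(pairs, ids) {
  all_ids <- vapply(pairs, function(p) p$id, character(1))
  idx <- match(ids, all_ids)
  if (anyNA(idx)) stop("split references pair ids absent from the pair list")
  pairs[idx]
}

#' Group pairs into full mini-batches
#'
#' Shuffles the pairs under `seed` and groups them into batches of exactly
#' `batch_size`; the remainder (`n mod batch_size` pairs) is randomly
#' excluded for this epoch, mirroring the dropped samples of a
#' batch-divisible training protocol. The excluded indices are attached as
#' the `"dropped"` attribute and reported via `message()`.
#'
#' @param pairs list of pairs (or any list; only its length is used).
#' @param batch_size batch size (default 16); must not exceed the number of
#'   pairs.
#' @param seed integer seed.
#' @param quiet suppress the exclusion message.
#' @return list of integer index vectors, one per batch, with attribute
#'   `"dropped"`.
#' @export
make_batches <- function(pairs, batch_size = 16L, seed = 1L, quiet = FALSE) {
  n <- length(pairs)
  batch_size <- as.integer(batch_size)
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (batch_size > n) {
    stop(sprintf("batch_size (%d) exceeds the number of pairs (%d)",
                 batch_size, n))
  }
  perm <- with_seed(seed, sample.int(n))
  n_batches <- n %/% batch_size
  kept <- perm[seq_len(n_batches * batch_size)]
  dropped <- perm[-seq_len(n_batches * batch_size)]
  if (length(dropped) > 0 && !quiet) {
    message(sprintf("make_batches: randomly excluded %d of %d pairs ",
                    length(dropped), n),
            "to keep the epoch divisible by the batch size")
  }
  batches <- split(kept, rep(seq_len(n_batches), each = batch_size))
  names(batches) <- NULL
  attr(batches, "dropped") <- dropped
  batches
}
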