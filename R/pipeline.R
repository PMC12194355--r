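# Reproducible end-to-end commands: simulate -> train -> evaluate, driven by
# a single structured configuration whose global seed derives every other
# seed.

#' Default run configuration
#'
#' A flat, sectioned, human-editable configuration (serialized as YAML) with
#' defaults equal to the study protocol's hyperparameters. Every stochastic
#' operation's seed is derived from the global `seed`.
#'
#' @return nested list with sections `phantom`, `model`, `training`,
#'   `metrics`, `paths` and a global `seed`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(
      n_subjects = 8L,
      regions = c("pelvis", "thorax"),
      fractions = protocol_fractions(low_only = TRUE),
      image_size = c(64L, 64L),
      background_rate = 10,
      bone_rate_scale = 5
    ),
    model = list(
      encoder_widths = c(32L, 64L),
      attention_reduction = 8L,
      gn_groups = 8L,
      erb_per_stage = 1L,
      output_activation = "sigmoid"
    ),
    training = list(
      loss_lambda = 0.7,
      learning_rate = 1e-3,
      batch_size = 16L,
      max_iterations = 2000L,
      patience = 50L,
      validate_every = 1L,
      val_max_pairs = NULL
    ),
    metrics = list(
      data_range = 255,
      ssim_window = 11L,
      ssim_sigma = 1.5
    ),
    split = list(
      ratios = c(0.75, 0.15, 0.10),
      group_by_subject = TRUE
    ),
    paths = list(
      data_dir = "data",
      checkpoint = "out/checkpoint.rds",
      out_dir = "out"
    )
  )
}

#' Read / write a run configuration (YAML)
#'
#' `read_run_config` merges the file over [default_run_config()] so partial
#' configs are valid; the round trip through YAML is lossless for all
#' settings.
#'
#' @param path YAML file path.
#' @param config a run-config list.
#' @return `read_run_config` returns the merged config list;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  user <- yaml::read_yaml(path)
  modifyList(default_run_config(), user)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

run_metric_config <- function(config) {
  metric_config(data_range = config$metrics$data_range,
                ssim_window = config$metrics$ssim_window,
                ssim_sigma = config$metrics$ssim_sigma)
}

run_model_config <- function(config) {
  m <- config$model
  model_config(encoder_widths = m$encoder_widths,
               decoder_widths = m$decoder_widths,
               attention_reduction = m$attention_reduction,
               gn_groups = m$gn_groups,
               erb_per_stage = m$erb_per_stage,
               output_activation = m$output_activation,
               init_seed = derive_seed(config$seed, 101L))
}

#' Simulate the paired low/full-dose dataset
#'
#' Calls [generate_paired_dataset()] with the `phantom` section of the
#' configuration and prints pair counts per region and fraction.
#'
#' @param config a run-config list (see [default_run_config()]).
#' @return the manifest data.frame, invisibly.
#' @export
cmd_simulate <- function(config = default_run_config()) {
  ph <- config$phantom
  manifest <- generate_paired_dataset(
    n_subjects = ph$n_subjects, regions = ph$regions,
    fractions = ph$fractions, base_seed = derive_seed(config$seed, 1L),
    out_dir = config$paths$data_dir,
    image_size = ph$image_size,
    background_rate = ph$background_rate,
    bone_rate_scale = ph$bone_rate_scale)
  counts <- table(manifest$region, manifest$dose_fraction)
  message(sprintf("simulate: %d pairs written to %s (seed %d)",
                  nrow(manifest), config$paths$data_dir, config$seed))
  for (r in rownames(counts)) {
    message(sprintf("  %s: %s", r,
                    paste(sprintf("%s%%:%d", as.numeric(colnames(counts)) * 100,
                                  counts[r, ]), collapse = " ")))
  }
  invisible(manifest)
}

#' Train the denoiser on a simulated dataset
#'
#' Builds pairs from the manifest, splits them (persisting the assignment as
#' JSON next to the checkpoint), trains the autoencoder and saves the
#' checkpoint plus the per-iteration history CSV.
#'
#' @param config a run-config list.
#' @return the training result list, invisibly.
#' @export
cmd_train <- function(config = default_run_config()) {
  manifest_path <- file.path(config$paths$data_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s (run cmd_simulate first)",
                 manifest_path))
  }
  pairs <- build_pairs(manifest_path)
  split <- split_dataset(pairs, ratios = config$split$ratios,
                         seed = derive_seed(config$seed, 2L),
                         group_by_subject = config$split$group_by_subject)
  dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_split(split, file.path(config$paths$out_dir, "split.json"))
  mc <- run_model_config(config)
  params <- init_ecae(mc)
  tcfg <- do.call(training_config, c(config$training,
                                     list(seed = derive_seed(config$seed, 3L))))
  fit <- train_ecae(params, mc, pairs_by_id(pairs, split$train),
                    pairs_by_id(pairs, split$validation), tcfg)
  save_checkpoint(config$paths$checkpoint, fit$params, mc,
                  history = fit$history,
                  seeds = list(global = config$seed,
                               init = mc$init_seed, train = tcfg$seed))
  write.csv(fit$history,
            file.path(config$paths$out_dir, "training_history.csv"),
            row.names = FALSE)
  message(sprintf(
    "train: %d train / %d val pairs, stopped by %s at iteration %d (best %d, val loss %.5f); checkpoint %s",
    length(split$train), length(split$validation), fit$stop_reason,
    max(fit$history$iteration), fit$best_iteration, fit$best_val_loss,
    config$paths$checkpoint))
  invisible(fit)
}

#' Evaluate the trained denoiser on the held-out test split
#'
#' Loads the checkpoint and the persisted split, evaluates only test-split
#' pairs (asserting no overlap with train/validation), and writes the
#' per-pair metric records and the per-dose summary as CSVs.
#'
#' @param config a run-config list.
#' @param identity_denoiser debug flag passed to [evaluate_pairs()].
#' @return list(records, summary), invisibly.
#' @export
cmd_evaluate <- function(config = default_run_config(),
                         identity_denoiser = FALSE) {
  ck <- load_checkpoint(config$paths$checkpoint)
  split <- read_split(file.path(config$paths$out_dir, "split.json"))
  pairs <- build_pairs(file.path(config$paths$data_dir, "manifest.csv"))
  if (length(intersect(split$test, c(split$train, split$validation))) > 0) {
    stop("split assignment is corrupt: test overlaps train/validation")
  }
  test_pairs <- pairs_by_id(pairs, split$test)
  records <- evaluate_pairs(ck$params, ck$config, test_pairs,
                            config = run_metric_config(config),
                            identity_denoiser = identity_denoiser)
  summary <- summarize_by_dose(records)
  dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(records, file.path(config$paths$out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(summary, file.path(config$paths$out_dir, "summary.csv"),
            row.names = FALSE)
  message(sprintf("evaluate: %d test pairs over %d dose levels -> %s",
                  nrow(records), nrow(summary),
                  file.path(config$paths$out_dir, "summary.csv")))
  invisible(list(records = records, summary = summary))
}

#' Denoise standalone images with a trained checkpoint
#'
#' @param config a run-config list (for the checkpoint path).
#' @param inputs character vector of grayscale PNG paths.
#' @param out_dir directory for the denoised PNGs.
#' @return character vector of output paths, invisibly.
#' @export
cmd_denoise <- function(config, inputs, out_dir) {
  ck <- load_checkpoint(config$paths$checkpoint)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- lapply(inputs, read_grayscale)
  den <- denoise_images(ck$params, ck$config, imgs)
  outs <- file.path(out_dir, paste0("denoised_", basename(inputs)))
  for (i in seq_along(outs)) write_grayscale(den[[i]], outs[i])
  message(sprintf("denoise: %d images -> %s", length(outs), out_dir))
  invisible(outs)
}

#' Paired t-test or TOST on two columns of a CSV
#'
#' @param csv_path CSV file path.
#' @param col_a,col_b column names of the paired samples.
#' @param test `"paired_t"` or `"tost"`.
#' @param delta TOST equivalence half-width.
#' @return the `"stat_result"`, invisibly (also printed).
#' @export
cmd_stats <- function(csv_path, col_a, col_b,
                      test = c("paired_t", "tost"), delta = 1.0) {
  test <- match.arg(test)
  df <- read.csv(csv_path)
  for (cl in c(col_a, col_b)) {
    if (!cl %in% names(df)) stop(sprintf("column %s not in %s", cl, csv_path))
  }
  res <- if (test == "paired_t") {
    paired_t_test(df[[col_a]], df[[col_b]])
  } else {
    tost_equivalence(df[[col_a]], df[[col_b]], delta = delta)
  }
  print(res)
  invisible(res)
}
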