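#' Read and validate an experiment configuration
#'
#' The YAML file mirrors the package's stages with sections `phantoms`,
#' `split`, `sampling`, `patches`, `model`, `train` and `segmentation`,
#' plus a global `seed`. Missing required sections raise an error naming
#' the section; omitted fields fall back to the package defaults.
#'
#' @param path Path to a YAML config.
#' @return Object of class `experiment_config` (a validated nested list).
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("phantoms", "split", "model", "train", "segmentation")
  for (sec in required)
    if (is.null(cfg[[sec]]))
      stop("experiment config: missing required section '", sec, "'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$sampling)) cfg$sampling <- list()
  if (is.null(cfg$patches)) cfg$patches <- list()
  structure(cfg, class = "experiment_config")
}

.cfg_get <- function(sec, name, default) {
  v <- sec[[name]]
  if (is.null(v)) default else v
}

#' Run the full phantom-to-metrics pipeline
#'
#' Generates a phantom cohort, splits it into train/validation/test,
#' draws weighted training voxels, trains the network, segments every test
#' phantom and writes per-case metrics. All stages derive their seeds from
#' the config's global seed, so a run is reproducible from
#' `(config, seed)` alone.
#'
#' Outputs in `out_dir`: `masks/<id>_pred.nii.gz` + ground truth +
#' result sidecar JSON per test case, `metrics.csv` (per-case rows),
#' `summary.csv`, `history.csv` (training log) and `run_log.txt`.
#'
#' @param config An `experiment_config` (or path to its YAML).
#' @param out_dir Output directory (created if missing).
#' @param verbose Log to console as well as to the run log.
#' @return Invisibly, a list with `metrics` (the [evaluate_cohort()]
#'   output), `model` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  seed <- as.integer(config$seed)
  ph <- config$phantoms

  base_cfg <- phantom_config(
    radius_vox = .cfg_get(ph, "radius_vox", 5),
    shape = unlist(.cfg_get(ph, "shape", c(20L, 44L, 44L))),
    spacing = unlist(.cfg_get(ph, "spacing", c(2.0, 0.7, 0.7))),
    noise_sd = .cfg_get(ph, "noise_sd", 30))
  kind_mix <- unlist(.cfg_get(ph, "kind_mix", c(isolated = 1)))
  n <- .cfg_get(ph, "n_phantoms", 20L)
  logf("generating %d phantoms (seed %d)", n, seed)
  cohort <- generate_cohort(n, kind_mix, base_cfg, seed = seed)

  sp <- config$split
  n_train <- .cfg_get(sp, "train", ceiling(0.6 * n))
  n_val <- .cfg_get(sp, "val", max(1L, floor(0.1 * n)))
  if (n_train + n_val >= n)
    stop("run_pipeline: split leaves no test phantoms")
  train_set <- cohort[seq_len(n_train)]
  val_set <- cohort[n_train + seq_len(n_val)]
  test_set <- cohort[(n_train + n_val + 1L):n]

  sampling <- config$sampling
  fraction <- .cfg_get(sampling, "fraction", 0.40)
  margin <- .cfg_get(sampling, "margin", 8L)
  logf("weighted sampling: fraction %.2f, margin %d", fraction, margin)
  maps <- unlist(lapply(train_set, function(s)
    build_weight_maps(s$volume, s$mask, margin)), recursive = FALSE)
  samples_df <- sample_training_voxels(maps, fraction, seed = seed + 1L)

  pc <- config$patches
  spec <- patch_spec(size_2d = .cfg_get(pc, "size_2d", 35L),
                     size_2d_large = .cfg_get(pc, "size_2d_large", 65L),
                     normalize_2d = .cfg_get(pc, "normalize_2d", TRUE))
  vols <- stats::setNames(lapply(train_set, `[[`, "volume"),
                          vapply(train_set, function(s) s$volume$volume_id, ""))
  logf("extracting %d training patch pairs", nrow(samples_df))
  pairs <- lapply(seq_len(nrow(samples_df)), function(i) {
    r <- samples_df[i, ]
    extract_patch_pair(vols[[r$volume_id]], c(r$slice, r$row, r$col), spec)
  })

  mc <- config$model
  mcfg <- model_config(input_size = spec$size_2d,
                       tiny = .cfg_get(mc, "tiny", TRUE),
                       pooling = .cfg_get(mc, "pooling", "central"))
  tr <- config$train
  tcfg <- train_config(base_lr = .cfg_get(tr, "base_lr", 6e-5),
                       gamma = .cfg_get(tr, "gamma", 1e-4),
                       power = .cfg_get(tr, "power", 0.75),
                       momentum = .cfg_get(tr, "momentum", 0.9),
                       batch_size = .cfg_get(tr, "batch_size", 128L),
                       max_epochs = .cfg_get(tr, "max_epochs", 21L),
                       patience = .cfg_get(tr, "patience", 3L),
                       seed = seed + 2L)
  threshold <- .cfg_get(config$segmentation, "threshold", 0.5)
  model <- build_model(mcfg, seed = seed + 2L)
  logf("training %d-parameter model for <= %d epochs",
       count_parameters(model), tcfg$max_epochs)
  t0 <- Sys.time()
  model <- train(model, pairs, samples_df$label, val_set, tcfg,
                 threshold = threshold, spec = spec, verbose = verbose)
  logf("training done in %.1f s (best val DSC %.3f)",
       as.numeric(difftime(Sys.time(), t0, units = "secs")),
       max(model$history$val_dsc))
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  save_checkpoint(model, file.path(out_dir, "model.ckpt"))

  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  results <- lapply(test_set, function(s) {
    res <- segment(model, s$volume, s$start_box, threshold = threshold,
                   spec = spec)
    id <- s$volume$volume_id
    write_mask(res$mask, s$volume, file.path(mask_dir, paste0(id, "_pred.nii.gz")))
    write_mask(s$mask, s$volume, file.path(mask_dir, paste0(id, "_gt.nii.gz")))
    jsonlite::write_json(
      list(volume_id = id,
           per_slice_area = as.list(res$per_slice_area),
           stop_reason_up = res$stop_reason_up,
           stop_reason_down = res$stop_reason_down),
      file.path(mask_dir, paste0(id, "_result.json")), auto_unbox = TRUE)
    res
  })
  metrics <- evaluate_cohort(results,
                             lapply(test_set, `[[`, "mask"),
                             lapply(test_set, function(s) s$volume$spacing),
                             ids = vapply(test_set, function(s) s$volume$volume_id, ""))
  utils::write.csv(metrics$per_case, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  logf("test mean DSC %.3f over %d phantoms",
       mean(metrics$per_case$dsc), nrow(metrics$per_case))
  invisible(list(metrics = metrics, model = model, out_dir = out_dir))
}
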