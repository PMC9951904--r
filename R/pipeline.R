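#' Map an 8-bit stored slice back to Hounsfield units
#'
#' Slice images are exported to disk through a fixed affine map from the HU
#' range `hu_range` to `[0, 1]` (see [write_slice_image()]); this inverts it
#' so the preprocessing chain can run on HU as it would for DICOM input.
#'
#' @param slice A [ct_slice] read from an exported image (values in
#'   `[0, 1]`).
#' @param hu_range The affine export range (default `c(-160, 240)`).
#' @return A [ct_slice] in HU, `intensity_state = "raw_hu"`.
#' @export
image_to_hu <- function(slice, hu_range = c(-160, 240)) {
  m <- as_pixel_matrix(slice)
  ct_slice(m * (hu_range[2] - hu_range[1]) + hu_range[1],
           slice$patient_id, slice$slice_index, "raw_hu")
}

#' Assemble a run configuration
#'
#' One object holding the per-stage configurations of the end-to-end
#' pipeline. Defaults are desk-scale: a small phantom cohort and a reduced
#' network that trains in minutes on one CPU; the preprocessing and
#' training defaults (window `[-100, 200]`, threshold 0.5, Adam at `1e-3`,
#' batch 3) follow the reference protocol.
#'
#' @param seed Global seed propagated to every stochastic stage.
#' @param n_patients Number of phantom patients.
#' @param slices_per_patient Integer interval of slices per patient.
#' @param side Network input side (phantoms are generated at this size).
#' @param base_filters Reduced network width (64 = full size).
#' @param epochs Training epochs.
#' @param batch_size Training batch size.
#' @param augment Apply the six-view augmentation to training pairs.
#' @param test_fraction,val_fraction Patient-level split fractions.
#' @param threshold Decision threshold for mask binarisation.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, n_patients = 5L,
                       slices_per_patient = c(4L, 6L), side = 64L,
                       base_filters = 4L, epochs = 2L, batch_size = 3L,
                       augment = FALSE, test_fraction = 0.2,
                       val_fraction = 0.3, threshold = 0.5) {
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 side = as.integer(side), base_filters = as.integer(base_filters),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), test_fraction = test_fraction,
                 val_fraction = val_fraction, threshold = threshold),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage_manifest <- function(dir, stage, inputs, outputs, seed, extra = list()) {
  man <- c(list(stage = stage, inputs = inputs, outputs = outputs,
                seed = seed, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("aimunet"))),
           extra)
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  man
}

#' Run the end-to-end pipeline
#'
#' simulate -> preprocess -> patient-level split -> (optional) augment ->
#' train -> predict -> threshold -> evaluate. Every stage writes a manifest
#' (inputs, outputs, seed); rerunning with the same configuration and seed
#' reproduces the evaluation CSV.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @param verbose Print stage progress.
#' @return List with `summary` (aggregated test metrics), `history`
#'   (training history), `paths` (key artifact locations).
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir) || !nzchar(out_dir))
    stop("validation error: `out_dir` is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  # --- stage 1: simulate ---------------------------------------------------
  say("[simulate] %d phantom patients", config$n_patients)
  data_dir <- file.path(out_dir, "data")
  pcfg <- phantom_config(height = config$side, width = config$side,
                         seed = config$seed)
  manifest <- generate_dataset(pcfg, data_dir, config$n_patients,
                               config$slices_per_patient)
  stage_manifest(out_dir, "simulate", inputs = list(),
                 outputs = data_dir, seed = config$seed,
                 list(n_patients = config$n_patients))

  # --- stage 2: preprocess + split ----------------------------------------
  say("[preprocess] window/equalize/resize/normalize")
  pids <- names(manifest)
  split <- split_patients(pids, config$test_fraction, config$val_fraction,
                          seed = config$seed)
  load_pair <- function(entry, pid) {
    rp <- read_slice_pair(entry$image, entry$mask_liver, pid, entry$slice_index)
    sl <- preprocess_slice(image_to_hu(rp$slice), side = config$side)
    list(x = sl, y = rp$mask, slice = sl, mask = rp$mask)
  }
  sets <- lapply(split, function(ids) {
    out <- list()
    for (pid in ids)
      for (entry in manifest[[pid]])
        out <- c(out, list(c(load_pair(entry, pid), list(pid = pid,
                                                         idx = entry$slice_index))))
    out
  })
  jsonlite::write_json(split, file.path(out_dir, "split.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  stage_manifest(out_dir, "preprocess", inputs = data_dir,
                 outputs = file.path(out_dir, "split.json"),
                 seed = config$seed,
                 list(n_train = length(sets$train), n_val = length(sets$val),
                      n_test = length(sets$test)))

  # --- stage 3: train ------------------------------------------------------
  train_pairs <- sets$train
  if (config$augment) {
    say("[augment] 7x expansion of %d training pairs", length(train_pairs))
    aug <- augment_dataset(lapply(train_pairs, function(p)
      list(slice = p$slice, mask = p$mask)),
      augmentation_policy(seed = config$seed))
    train_pairs <- lapply(aug, function(p) list(x = p$slice, y = p$mask))
  }
  say("[train] %d pairs, %d epochs", length(train_pairs), config$epochs)
  net <- build_aim_unet(network_config(
    input_height = config$side, input_width = config$side,
    base_filters = config$base_filters))
  fit <- train(net, train_pairs,
               train_config(batch_size = config$batch_size,
                            epochs = config$epochs, seed = config$seed),
               verbose = verbose)
  hist_path <- file.path(out_dir, "history.csv")
  utils::write.csv(fit$history, hist_path, row.names = FALSE)
  stage_manifest(out_dir, "train", inputs = data_dir, outputs = hist_path,
                 seed = config$seed, list(steps = fit$steps))

  # --- stage 4: predict + postprocess -------------------------------------
  say("[predict] %d test slices", length(sets$test))
  pred_dir <- file.path(out_dir, "pred"); truth_dir <- file.path(out_dir, "truth")
  dir.create(pred_dir, showWarnings = FALSE); dir.create(truth_dir, showWarnings = FALSE)
  by_pid <- split(sets$test, vapply(sets$test, `[[`, character(1), "pid"))
  for (pid in names(by_pid)) {
    masks <- list()
    for (p in by_pid[[pid]]) {
      pm <- predict_slice(net, fit$weights, p$slice)
      mk <- binarize(pm, config$threshold)
      attr(mk, "patient_id") <- pid
      masks <- c(masks, list(mk))
      fname <- sprintf("%s_%04d.png", pid, p$idx)
      write_mask_png(mk, file.path(pred_dir, fname))
      write_mask_png(p$mask, file.path(truth_dir, fname))
    }
    vol <- stack_volume(masks, pid)
    write_nifti(vol, file.path(pred_dir, paste0(pid, ".nii.gz")))
  }
  stage_manifest(out_dir, "predict", inputs = hist_path, outputs = pred_dir,
                 seed = config$seed)

  # --- stage 5: evaluate ---------------------------------------------------
  say("[evaluate]")
  ev <- evaluate_masks(pred_dir, truth_dir)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(ev$per_slice, metrics_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "metrics_summary.csv")
  utils::write.csv(ev$summary, summary_path, row.names = FALSE)
  stage_manifest(out_dir, "evaluate", inputs = pred_dir,
                 outputs = metrics_path, seed = config$seed)
  list(summary = ev$summary, history = fit$history,
       paths = list(data = data_dir, history = hist_path,
                    predictions = pred_dir, metrics = metrics_path))
}
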