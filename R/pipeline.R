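# End-to-end workflow: simulate a phantom cohort, build the dataset
# manifest, train, infer on the test patients, measure and classify DSA,
# and emit the evaluation report.  One structured config drives a run; all
# randomness flows from one root seed split per stage.

#' Pipeline run configuration
#'
#' Nested configuration for [run_pipeline()].  Unknown keys are rejected so
#' that a config file cannot silently misspell an option.
#'
#' @param seed root RNG seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @param cohort list: n_dev / n_test patient counts.
#' @param geometry list: slice_px, pixel_mm of the reformatted slices.
#' @param model list: depth, base_channels, inference_decoder.
#' @param training list: epochs, learning_rate, batch_size, lambda.
#' @param phantom list of overrides for [phantom_config()] (geometry of the
#'   simulated spines; per-level areas are drawn per patient).
#' @return A list of class \code{run_config}.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("duralseg_run_"),
                            cohort = list(), geometry = list(),
                            model = list(), training = list(),
                            phantom = list()) {
  merge_known <- function(defaults, given, what) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop(sprintf("unknown %s option(s): %s", what,
                   paste(bad, collapse = ", ")))
    defaults[names(given)] <- given
    defaults
  }
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    cohort = merge_known(list(n_dev = 2, n_test = 1), cohort, "cohort"),
    geometry = merge_known(list(slice_px = 64, pixel_mm = 0.75), geometry,
                           "geometry"),
    model = merge_known(list(depth = 4, base_channels = 16,
                             inference_decoder = "A"), model, "model"),
    training = merge_known(list(epochs = 50, learning_rate = 0.001,
                                batch_size = 8, lambda = 1), training,
                           "training"),
    phantom = phantom)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline config from a YAML file
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A \code{run_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "cohort", "geometry", "model", "training",
             "phantom")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' simulate -> build-dataset -> train -> infer -> classify -> evaluate.
#' Every artifact under \code{out_dir} is regenerable from (config, seed);
#' re-running with the same config reproduces the evaluation tables
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the evaluation report, file paths, and
#'   the training history.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$cohort$n_dev < 1)
    stop("no development patients: cannot train without labeled data")
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "runlog.txt")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                            sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("run start; root seed %d", config$seed)
  logf("config: %s", paste(deparse(unclass(config)), collapse = " "))
  seeds <- with_seed(config$seed, sample.int(2^31 - 1, 6))
  logf("stage seeds: %s", paste(seeds, collapse = " "))
  gm <- config$geometry
  fov <- gm$slice_px * gm$pixel_mm

  # --- simulate + reformat -----------------------------------------------
  n_pat <- config$cohort$n_dev + config$cohort$n_test
  ids <- sprintf("P%03d", seq_len(n_pat))
  split_plan <- c(train = config$cohort$n_dev, validation = 0,
                  test = config$cohort$n_test)
  manifest <- build_manifest(ids, split_plan, seed = seeds[1])
  write_manifest(manifest, file.path(out, "manifest.csv"))
  logf("manifest: %d rows", nrow(manifest))
  slices <- list()  # keyed by patient|mode|level|offset
  for (i in seq_len(n_pat)) {
    pcfg <- do.call(random_phantom_config,
                    c(list(seed = seeds[2] %% 100000L + i * 37L),
                      config$phantom))
    ph <- generate_phantom(pcfg)
    write_volume(ph$volume, file.path(out, paste0(ids[i], "_clean.nii.gz")))
    write_volume(ph$label, file.path(out, paste0(ids[i], "_label.nii.gz")))
    for (mode in c("lumbar", "abdominal")) {
      sl <- phantom_slices(ph, mode, fov_mm = fov, pixel_mm = gm$pixel_mm,
                           seed = seeds[2] %% 100000L + i * 37L +
                             (mode == "abdominal"))
      for (s in sl)
        slices[[paste(ids[i], mode, s$level, s$offset_mm, sep = "|")]] <- s
    }
    logf("simulated %s (5 levels x 2 modes)", ids[i])
  }

  # --- assemble training data from the manifest --------------------------
  mk <- paste(manifest$patient_id, manifest$mode, manifest$level,
              manifest$offset_mm, sep = "|")
  dev_rows <- manifest$split %in% c("train", "validation")
  labeled <- lapply(which(dev_rows & manifest$labeled), function(r)
    slices[[mk[r]]][c("image", "mask")])
  unlabeled <- lapply(which(dev_rows & !manifest$labeled), function(r)
    slices[[mk[r]]]$image)
  if (length(labeled) == 0) stop("no labeled training data in the manifest")

  # --- train --------------------------------------------------------------
  model <- build_model(unet_config(
    input_size = c(gm$slice_px, gm$slice_px), depth = config$model$depth,
    base_channels = config$model$base_channels,
    inference_decoder = config$model$inference_decoder, seed = seeds[3]))
  fit <- train_model(model, labeled, unlabeled, training_config(
    epochs = config$training$epochs,
    learning_rate = config$training$learning_rate,
    batch_size = config$training$batch_size,
    lambda = config$training$lambda, seed = seeds[4]))
  write.csv(fit$history, file.path(out, "history.csv"), row.names = FALSE)
  save_model(fit$model, file.path(out, "model.rds"))
  logf("trained: %d epochs, final supervised loss %.4f",
       config$training$epochs, tail(fit$history$supervised, 1))

  # --- infer + measure on the test split ----------------------------------
  test_rows <- which(manifest$split == "test")
  preds <- do.call(rbind, lapply(test_rows, function(r) {
    s <- slices[[mk[r]]]
    pm <- predict_mask(fit$model, s$image)
    data.frame(patient_id = manifest$patient_id[r], mode = manifest$mode[r],
               level = manifest$level[r], offset_mm = manifest$offset_mm[r],
               dsa_mm2 = dsa_from_mask(pm, gm$pixel_mm),
               dice = dice(pm, s$mask))
  }))
  truth <- do.call(rbind, lapply(test_rows, function(r) {
    s <- slices[[mk[r]]]
    data.frame(patient_id = manifest$patient_id[r], mode = manifest$mode[r],
               level = manifest$level[r], offset_mm = manifest$offset_mm[r],
               dsa_mm2 = s$ref_dsa_mm2)
  }))
  write.csv(preds, file.path(out, "measurements.csv"), row.names = FALSE)
  logf("inference: %d test slices", nrow(preds))

  # --- classify + evaluate -------------------------------------------------
  levels_tab <- summarize_levels(preds)
  write.csv(levels_tab, file.path(out, "levels.csv"), row.names = FALSE)
  report <- evaluate_testset(preds, truth)
  write.csv(report$strata, file.path(out, "report_strata.csv"),
            row.names = FALSE)
  con <- file(file.path(out, "report.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  logf("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(report = report, history = fit$history,
                 measurements = preds, levels = levels_tab,
                 out_dir = out))
}
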