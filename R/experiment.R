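# Phantom cohort helpers and the synthetic recovery experiment: train the
# dual-decoder U-Net on phantom slices with a small labeled set and measure
# held-out segmentation quality, with and without the consistency term.

# one random phantom: per-level DSA drawn uniformly over 45-140 mm2 so the
# cohort spans normal, stenosis and severe-stenosis levels
random_phantom_config <- function(seed, mode = "lumbar", ...) {
  areas <- with_seed(seed, runif(5, 45, 140))
  names(areas) <- DISC_LEVELS
  amp <- with_seed(seed + 1L, runif(1, 3, 8))
  phantom_config(level_dsa_mm2 = areas, curve_amplitude_mm = amp,
                 mode = mode, seed = seed, ...)
}

# reformat all five levels of one phantom in one acquisition mode into
# per-slice records: image, mask, level, offset, measured reference DSA
phantom_slices <- function(phantom, mode, fov_mm = 48, pixel_mm = 0.75,
                           noise_sd_hu = 10, seed = 1) {
  vol <- apply_acquisition_mode(phantom$volume, phantom$label, mode,
                                noise_sd_hu = noise_sd_hu, seed = seed)
  cent <- locate_centroids(vol)
  curve <- fit_spinal_curve(cent)
  dc <- disc_centers(curve)
  s_dc <- attr(dc, "s")
  out <- list()
  for (l in seq_along(s_dc)) {
    st <- reformat_level(vol, curve, s_dc[l], label = phantom$label,
                         level = DISC_LEVELS[l], fov_mm = fov_mm,
                         pixel_mm = pixel_mm)
    for (i in seq_along(st$offsets_mm)) {
      mask <- (st$label_slices[, , i] == label_codes()[["dural_sac"]]) * 1L
      out[[length(out) + 1]] <- list(
        image = st$slices[, , i], mask = mask,
        level = DISC_LEVELS[l], offset_mm = st$offsets_mm[i], mode = mode,
        ref_dsa_mm2 = dsa_from_mask(mask, pixel_mm),
        true_dsa_mm2 = phantom$truth$dsa_profile[l, i])
    }
  }
  out
}

#' Synthetic segmentation recovery experiment
#'
#' Trains the dual-decoder U-Net on phantom slices (a small labeled set plus
#' an unlabeled pool, as in the semi-supervised design) and reports the mean
#' Dice coefficient on slices from a held-out phantom.  Used to verify that
#' the training loop recovers high-quality segmentations and that the
#' consistency term does not hurt.
#'
#' @param n_labeled,n_unlabeled training slice counts.
#' @param slice_px reformatted slice size in pixels (square).
#' @param pixel_mm in-plane pixel spacing of the reformatted slices.
#' @param epochs,batch_size training settings (see [training_config()]).
#' @param lambda consistency weight(s); several values share the same
#'   phantom slices, initialization and data order, isolating the effect of
#'   the consistency term.
#' @param seed RNG seed; drives phantom sampling, slice assignment,
#'   initialization, shuffling and augmentation.
#' @param n_eval number of held-out slices to evaluate.
#' @return List: \code{dsc} (named per-lambda mean held-out Dice),
#'   \code{history} (per-lambda), \code{models}, and the
#'   training/evaluation slice counts.
#' @export
recovery_experiment <- function(n_labeled = 40, n_unlabeled = 160,
                                slice_px = 64, pixel_mm = 0.75,
                                epochs = 50, lambda = 1, batch_size = 8,
                                seed = 1, n_eval = 60) {
  fov <- slice_px * pixel_mm
  n_train_phantoms <- ceiling((n_labeled + n_unlabeled) / 110)
  slices <- list()
  for (p in seq_len(n_train_phantoms)) {
    ph <- generate_phantom(random_phantom_config(seed * 101L + p))
    for (mode in c("lumbar", "abdominal"))
      slices <- c(slices, phantom_slices(ph, mode, fov_mm = fov,
                                         pixel_mm = pixel_mm,
                                         seed = seed * 7L + p))
  }
  idx <- with_seed(seed + 13L, sample(length(slices)))
  lab_idx <- idx[seq_len(n_labeled)]
  unlab_idx <- idx[n_labeled + seq_len(min(n_unlabeled,
                                           length(idx) - n_labeled))]
  labeled <- lapply(slices[lab_idx], function(s) s[c("image", "mask")])
  unlabeled <- lapply(slices[unlab_idx], function(s) s$image)
  hp <- generate_phantom(random_phantom_config(seed * 101L + 977L))
  eval_slices <- c(phantom_slices(hp, "lumbar", fov_mm = fov,
                                  pixel_mm = pixel_mm, seed = seed + 55L),
                   phantom_slices(hp, "abdominal", fov_mm = fov,
                                  pixel_mm = pixel_mm, seed = seed + 56L))
  eval_slices <- eval_slices[with_seed(seed + 77L,
    sample(length(eval_slices), min(n_eval, length(eval_slices))))]
  dsc <- numeric(0); history <- list(); models <- list()
  for (lam in lambda) {
    model <- build_model(unet_config(input_size = c(slice_px, slice_px),
                                     seed = seed))
    fit <- train_model(model, labeled,
                       if (lam > 0) unlabeled else list(),
                       training_config(epochs = epochs, lambda = lam,
                                       batch_size = batch_size, seed = seed))
    key <- paste0("lambda", lam)
    dsc[key] <- evaluate_dsc(fit$model, eval_slices)
    history[[key]] <- fit$history
    models[[key]] <- fit$model
  }
  list(dsc = dsc, history = history, models = models,
       n_labeled = length(labeled), n_unlabeled = length(unlabeled),
       n_eval = length(eval_slices))
}
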