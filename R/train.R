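# Semi-supervised training: cross-entropy on labeled slices plus an L2
# cross-decoder consistency penalty on unlabeled slices (mutual soft
# pseudo-labeling), optimized with Adam.

#' Training configuration
#'
#' @param epochs number of passes over the labeled set.
#' @param learning_rate Adam learning rate.
#' @param batch_size total slices per step; when unlabeled data are present,
#'   batches mix equal labeled and unlabeled halves so both loss terms stay
#'   active every step.
#' @param lambda weight of the consistency term.
#' @param augment an [augment_params()]; use [augment_identity()] to disable.
#' @param seed RNG seed driving shuffling and augmentation.
#' @return A list of class \code{training_config}.
#' @export
training_config <- function(epochs = 50, learning_rate = 0.001,
                            batch_size = 8, lambda = 1,
                            augment = augment_params(), seed = 1) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1, lambda >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), lambda = lambda,
                 augment = augment, seed = as.integer(seed)),
            class = "training_config")
}

#' Train a dual-decoder U-Net
#'
#' Per step, the objective is the supervised loss on the labeled half of the
#' batch plus \code{lambda} times the consistency loss on the unlabeled
#' half; with \code{lambda = 0} or no unlabeled data, training degenerates
#' to plain supervised dual-decoder training.  Slices are z-score normalized
#' after augmentation.  Fully reproducible given the config seed.
#'
#' @param model a [build_model()] result (modified in place).
#' @param labeled list of \code{list(image = matrix, mask = 0/1 matrix)}.
#' @param unlabeled list of image matrices (may be empty).
#' @param config a [training_config()].
#' @return List with the trained \code{model} and \code{history}, a
#'   data.frame of per-epoch mean supervised and consistency losses.
#' @export
train_model <- function(model, labeled, unlabeled = list(),
                        config = training_config()) {
  stopifnot(inherits(model, "dd_unet"), inherits(config, "training_config"))
  if (length(labeled) == 0) stop("labeled set is empty")
  set.seed(config$seed)
  # with lambda = 0 the unlabeled set cannot influence training (not even
  # through batch statistics), so it is skipped entirely
  use_unlab <- length(unlabeled) > 0 && config$lambda > 0
  nl_batch <- if (use_unlab)
    max(1L, config$batch_size %/% 2L) else config$batch_size
  nu_batch <- if (use_unlab) config$batch_size - nl_batch else 0L
  history <- data.frame(epoch = seq_len(config$epochs),
                        supervised = NA_real_, consistency = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(labeled))
    uord <- if (nu_batch > 0) sample(length(unlabeled)) else integer()
    up <- 0L
    sups <- c(); conss <- c()
    for (b0 in seq(1, length(ord), by = nl_batch)) {
      bl <- ord[b0:min(b0 + nl_batch - 1, length(ord))]
      li <- vector("list", length(bl)); lm <- vector("list", length(bl))
      for (k in seq_along(bl)) {
        a <- augment(labeled[[bl[k]]]$image, labeled[[bl[k]]]$mask,
                     config$augment)
        li[[k]] <- normalize_slice(a$image)
        lm[[k]] <- as.integer(a$mask)
      }
      ui <- list()
      if (nu_batch > 0) {
        ui <- vector("list", nu_batch)
        for (k in seq_len(nu_batch)) {
          up <- up + 1L
          if (up > length(uord)) { uord <- sample(length(unlabeled)); up <- 1L }
          a <- augment(unlabeled[[uord[up]]], NULL, config$augment)
          ui[[k]] <- normalize_slice(a$image)
        }
      }
      st <- nn_train_step(model$ptr, li, lm, ui, config$lambda,
                          config$learning_rate, 0.9, 0.999, 1e-8)
      sups <- c(sups, st$supervised)
      conss <- c(conss, st$consistency)
    }
    history$supervised[ep] <- mean(sups)
    history$consistency[ep] <- mean(conss)
  }
  list(model = model, history = history)
}

#' Mean Dice of a model on held-out slices
#'
#' @param model trained \code{dd_unet}.
#' @param slices list of \code{list(image, mask)}.
#' @param threshold binarization threshold.
#' @return Mean Dice coefficient over the slices.
#' @export
evaluate_dsc <- function(model, slices, threshold = 0.5) {
  mean(vapply(slices, function(s) {
    dice(predict_mask(model, s$image, threshold), s$mask)
  }, numeric(1)))
}
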