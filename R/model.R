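# Single-encoder, dual-decoder U-Net.  The compiled backend (src/nn.cpp)
# holds parameters and optimizer state; this file provides the configuration
# surface, construction, the forward pass, and checkpointing.

#' Dual-decoder U-Net configuration
#'
#' The contracting path is \code{depth} conv-batchnorm-ReLU double blocks
#' with 2x2 max pooling, channels doubling from \code{base_channels}.  Two
#' expansive paths share the encoder's skip connections by concatenation and
#' differ only in how they grow the feature maps: decoder A uses 2x2
#' stride-2 transposed convolutions, decoder B fixed nearest-neighbour
#' interpolation followed by a 3x3 convolution.
#'
#' @param input_size image size (H, W); both divisible by 2^depth.
#' @param depth number of pooling stages.
#' @param base_channels channels at the first stage.
#' @param n_classes output classes (background, dural sac).
#' @param inference_decoder decoder used at inference, \code{"A"} or
#'   \code{"B"}.
#' @param seed RNG seed for weight initialization.
#' @return A list of class \code{unet_config}.
#' @export
unet_config <- function(input_size = c(160, 160), depth = 4,
                        base_channels = 16, n_classes = 2,
                        inference_decoder = c("A", "B"), seed = 1) {
  inference_decoder <- match.arg(inference_decoder)
  stopifnot(length(input_size) == 2, base_channels >= 1, n_classes >= 2,
            depth >= 1)
  if (any(input_size %% 2^depth != 0))
    stop(sprintf("input size %dx%d is not divisible by 2^depth = %d; %s",
                 input_size[1], input_size[2], 2^depth,
                 "pooling would not halve the grid evenly at every stage"))
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 inference_decoder = inference_decoder,
                 seed = as.integer(seed)),
            class = "unet_config")
}

#' Build a dual-decoder U-Net
#'
#' Weight initialization (He-normal) is a pure function of the config seed:
#' building twice with the same config yields identical parameters.
#'
#' @param config a [unet_config()].
#' @return An object of class \code{dd_unet}.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  ptr <- nn_create(config$input_size[1], config$input_size[2], config$depth,
                   config$base_channels, config$n_classes, config$seed)
  structure(list(ptr = ptr, config = config), class = "dd_unet")
}

#' @export
print.dd_unet <- function(x, ...) {
  cat(sprintf("<dd_unet> %dx%d input, depth %d, base %d, %s parameters\n",
              x$config$input_size[1], x$config$input_size[2],
              x$config$depth, x$config$base_channels,
              format(nn_nparams(x$ptr), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [build_model()] result.
#' @return Parameter count.
#' @export
n_params <- function(model) nn_nparams(model$ptr)

#' Model parameters as a named list
#'
#' Used for checkpointing and for verifying that decoder A and decoder B
#' hold disjoint parameter sets behind the shared encoder.
#' @param model a \code{dd_unet}.
#' @return Named list of weight matrices and batch-norm running statistics.
#' @export
model_params <- function(model) nn_get_params(model$ptr)

#' Restore parameters into a model
#' @param model a \code{dd_unet}.
#' @param params a [model_params()] list with matching shapes.
#' @return The model, invisibly.
#' @export
set_model_params <- function(model, params) {
  nn_set_params(model$ptr, params)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the config, so [load_model()] rebuilds the network
#' and restores weights.
#' @param model a \code{dd_unet}.
#' @param path file path.
#' @return \code{path} / the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config, params = model_params(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$config)
  set_model_params(m, ck$params)
  m
}

#' Normalize a slice for the network
#'
#' Zero-mean / unit-variance per slice, the normalization the network is
#' trained with.
#' @param image numeric matrix.
#' @return Normalized matrix.
#' @export
normalize_slice <- function(image) {
  s <- sd(image)
  (image - mean(image)) / if (s > 0) s else 1
}

#' Forward pass
#'
#' @param model a \code{dd_unet}.
#' @param images a single matrix or list of matrices matching the configured
#'   input size, already normalized (see [normalize_slice()]).
#' @param phase \code{"train"} returns both decoders' probability maps (and
#'   uses batch statistics for normalization); \code{"inference"} returns
#'   only the configured inference decoder's map (using running statistics).
#' @return For each image, per-decoder probability arrays of size
#'   H x W x n_classes; a single image returns the arrays directly.
#' @export
forward <- function(model, images, phase = c("inference", "train")) {
  stopifnot(inherits(model, "dd_unet"))
  phase <- match.arg(phase)
  single <- is.matrix(images)
  if (single) images <- list(images)
  hw <- model$config$input_size
  for (im in images)
    if (!identical(dim(im), hw))
      stop(sprintf("image is %dx%d but the model expects %dx%d",
                   nrow(im), ncol(im), hw[1], hw[2]))
  dec <- if (phase == "train") 0L else
    if (model$config$inference_decoder == "A") 1L else 2L
  raw <- nn_forward(model$ptr, images, train = (phase == "train"), decoder = dec)
  shape <- function(p) array(p, c(hw[1], hw[2], model$config$n_classes))
  out <- lapply(seq_along(images), function(n) {
    r <- lapply(raw, function(d) shape(d[[n]]))
    if (phase == "inference") r[[1]] else r
  })
  if (single) out[[1]] else out
}

#' Predict a binary dural-sac mask
#'
#' Runs the inference decoder and binarizes the dural-sac probability at
#' \code{threshold}.
#' @param model a \code{dd_unet}.
#' @param image raw (unnormalized) slice matrix.
#' @param threshold probability cut, default 0.5.
#' @return Integer matrix mask (1 = dural sac).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- forward(model, normalize_slice(image), phase = "inference")
  (p[, , 2] >= threshold) * 1L
}
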