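# Data augmentation: elastic deformation, random scaling and rotation
# (spatial transforms shared by image and mask), Gaussian blur and Gaussian
# noise (photometric, image only).

#' Augmentation parameters
#'
#' @param elastic_alpha displacement magnitude of the elastic field, pixels.
#' @param elastic_sigma Gaussian smoothing of the elastic field, pixels.
#' @param scale multiplicative scale range.
#' @param rotation rotation range in degrees (+- rotation).
#' @param blur Gaussian blur sigma range, pixels.
#' @param noise_sd additive Gaussian noise sd, as a fraction of the image
#'   intensity range.
#' @param prob per-transform application probability.
#' @return A list of class \code{augment_params}.
#' @export
augment_params <- function(elastic_alpha = 10, elastic_sigma = 4,
                           scale = c(0.9, 1.1), rotation = 15,
                           blur = c(0, 1), noise_sd = 0.05, prob = 0.5) {
  stopifnot(elastic_alpha >= 0, elastic_sigma >= 0,
            length(scale) == 2, scale[1] <= scale[2], scale[1] > 0,
            rotation >= 0, length(blur) == 2, blur[1] <= blur[2],
            blur[1] >= 0, noise_sd >= 0, prob >= 0, prob <= 1)
  structure(list(elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 scale = scale, rotation = rotation, blur = blur,
                 noise_sd = noise_sd, prob = prob),
            class = "augment_params")
}

#' Identity augmentation parameters
#' @return [augment_params()] whose every range collapses to the identity.
#' @export
augment_identity <- function() {
  augment_params(elastic_alpha = 0, elastic_sigma = 0, scale = c(1, 1),
                 rotation = 0, blur = c(0, 0), noise_sd = 0, prob = 1)
}

#' Augment an image (and optionally its mask)
#'
#' The same spatial transform (rotation, scaling, elastic deformation about
#' the image centre) is applied to the image (bilinear) and the mask
#' (nearest-neighbour, so it stays binary); blur and noise touch the image
#' only.  Degenerate parameter ranges collapse to the identity.  Randomness
#' is drawn from the R RNG stream, so \code{set.seed()} makes augmented
#' pairs reproducible.
#'
#' @param image numeric matrix.
#' @param mask optional integer 0/1 matrix of the same shape.
#' @param params an [augment_params()].
#' @return List with elements \code{image} and \code{mask} (NULL when no
#'   mask was given).
#' @export
augment <- function(image, mask = NULL, params = augment_params()) {
  stopifnot(inherits(params, "augment_params"))
  if (!is.null(mask) && !identical(dim(mask), dim(image)))
    stop("mask must be aligned with the image")
  H <- nrow(image); W <- ncol(image)
  do_rot <- params$rotation > 0 && runif(1) < params$prob
  do_scale <- diff(params$scale) > 0 && runif(1) < params$prob
  do_elastic <- params$elastic_alpha > 0 && runif(1) < params$prob
  theta <- if (do_rot) runif(1, -params$rotation, params$rotation) * pi / 180 else 0
  sc <- if (do_scale) runif(1, params$scale[1], params$scale[2]) else 1
  if (do_rot || do_scale || do_elastic) {
    cx <- (H - 1) / 2; cy <- (W - 1) / 2
    gx <- rep(seq_len(H) - 1, times = W) - cx
    gy <- rep(seq_len(W) - 1, each = H) - cy
    # inverse affine: rotate by -theta, scale by 1/sc
    sx <- (cos(theta) * gx + sin(theta) * gy) / sc + cx
    sy <- (-sin(theta) * gx + cos(theta) * gy) / sc + cy
    if (do_elastic) {
      dx <- cpp_gaussian_blur(matrix(runif(H * W, -1, 1), H, W),
                              params$elastic_sigma)
      dy <- cpp_gaussian_blur(matrix(runif(H * W, -1, 1), H, W),
                              params$elastic_sigma)
      # rescale the smoothed field to the requested magnitude
      mx <- max(abs(range(dx)), abs(range(dy)), 1e-9)
      sx <- sx + as.numeric(dx) / mx * params$elastic_alpha
      sy <- sy + as.numeric(dy) / mx * params$elastic_alpha
    }
    fillv <- min(image)
    image <- matrix(cpp_sample_image(image, sx, sy, nearest = FALSE,
                                     fill = fillv), H, W)
    if (!is.null(mask))
      mask <- matrix(as.integer(cpp_sample_image(mask + 0, sx, sy,
                                                 nearest = TRUE, fill = 0)),
                     H, W)
  }
  if (params$blur[2] > 0 && runif(1) < params$prob) {
    sg <- runif(1, params$blur[1], params$blur[2])
    if (sg > 0) image <- cpp_gaussian_blur(image, sg)
  }
  if (params$noise_sd > 0 && runif(1) < params$prob) {
    rg <- diff(range(image))
    if (rg > 0)
      image <- image + matrix(rnorm(H * W, 0, params$noise_sd * rg), H, W)
  }
  list(image = image, mask = mask)
}
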