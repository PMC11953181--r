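# Training losses.  The compiled training step computes the same quantities;
# these reference implementations define the semantics and serve the tests.

#' Supervised segmentation loss
#'
#' Sum over the two decoders of the pixel-averaged cross-entropy between the
#' decoder's probability map and the binary label mask.  Probabilities are
#' clamped at 1e-7 for numerical stability, so a perfect prediction gives a
#' loss of at most \code{2 * 1e-7}-ish rather than exactly zero.
#'
#' @param output list with elements \code{A} and \code{B}, each an
#'   H x W x n_classes probability array (see [forward()] in train phase).
#' @param mask integer matrix of 0/1 labels (1 = dural sac).
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(output, mask) {
  if (is.null(output$A) || is.null(output$B))
    stop("both decoder outputs are required")
  if (!all(mask %in% c(0, 1)))
    stop("label mask must contain only classes 0 and 1")
  ce <- function(p) {
    pick <- ifelse(mask == 1, p[, , 2], p[, , 1])
    mean(-log(pmax(pick, 1e-7)))
  }
  ce(output$A) + ce(output$B)
}

#' Cross-decoder consistency loss
#'
#' L2 penalty between the two decoders' probability maps: squared
#' differences are summed over class channels and averaged over pixels.
#' Under this reduction, two one-hot maps that disagree on every pixel give
#' a loss of 2 (1 per class channel).  Symmetric; zero iff the maps are
#' identical.
#'
#' @param prob_a,prob_b probability arrays of identical shape
#'   (H x W x n_classes).
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(prob_a, prob_b) {
  if (!identical(dim(prob_a), dim(prob_b)))
    stop("probability maps must have identical shape")
  sum((prob_a - prob_b)^2) / prod(dim(prob_a)[1:2])
}
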