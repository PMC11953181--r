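#' CT volume container
#'
#' A minimal in-memory representation of a 3D CT volume: an intensity grid in
#' Hounsfield-unit-like values plus the geometry needed to map voxel indices
#' to world millimetres.  World position of voxel \code{(i,j,k)} (0-based) is
#' \code{origin + c(i,j,k) * spacing}; axes are x = left to right,
#' y = posterior to anterior, z = inferior to superior.
#'
#' @param intensities 3D numeric array.
#' @param spacing voxel spacing in mm, length 3, strictly positive.
#' @param origin world position of voxel (0,0,0) in mm.
#' @param mode acquisition mode, \code{"lumbar"} or \code{"abdominal"}.
#' @param patient_id identifier string.
#' @return An object of class \code{ct_volume}.
#' @export
ct_volume <- function(intensities, spacing, origin = c(0, 0, 0),
                      mode = "lumbar", patient_id = "anon") {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array, got dimensionality ",
         length(dim(intensities)))
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  mode <- match.arg(mode, c("lumbar", "abdominal"))
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mode = mode,
                 patient_id = patient_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %s [%s] %dx%dx%d voxels @ %.3gx%.3gx%.3g mm\n",
              x$patient_id, x$mode, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Label volume container
#'
#' Categorical companion of a [ct_volume()]: integer codes
#' 0 = background, 1 = bone, 2 = dural sac, 3 = disc posterior margin,
#' 4 = ligamentum flavum.
#'
#' @param classes 3D integer array of class codes.
#' @param spacing,origin geometry, as for [ct_volume()].
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(classes, spacing, origin = c(0, 0, 0)) {
  if (length(dim(classes)) != 3L) stop("classes must be a 3D array")
  if (!all(classes %in% 0:4))
    stop("labels must be drawn from codes 0 (background) to 4 (ligamentum flavum)")
  structure(list(classes = classes, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' Label code table
#' @return Named integer vector mapping class names to codes.
#' @export
label_codes <- function() {
  c(background = 0L, bone = 1L, dural_sac = 2L,
    disc_posterior_margin = 3L, ligamentum_flavum = 4L)
}

#' Read a CT volume from a NIfTI-1 file
#'
#' @param path file path (.nii or .nii.gz).
#' @param mode,patient_id metadata to attach (not stored in NIfTI).
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, mode = "lumbar", patient_id = "anon") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got dimensionality ", length(dim(arr)))
  attributes(arr) <- list(dim = dim(arr))
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("NIfTI header carries no usable voxel spacing")
  }
  origin <- as.numeric(xf[1:3, 4])
  ct_volume(arr, spacing = as.numeric(sp), origin = origin,
            mode = mode, patient_id = patient_id)
}

#' Write a CT or label volume as NIfTI-1
#'
#' Spacing and origin are stored in the sform affine (diagonal spacing plus
#' translation).  Intensities round-trip bit-exactly through [read_volume()].
#'
#' @param volume a [ct_volume()] or [label_volume()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- if (inherits(volume, "label_volume")) volume$classes else volume$intensities
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(arr, datatype = if (is.integer(arr)) "int" else "double")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
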