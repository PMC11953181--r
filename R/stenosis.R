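# DSA measurement from masks and stenosis classification.
# Clinical thresholds: stenosis when DSA < 100 mm2, severe stenosis when
# DSA < 75 mm2; a disc level is represented by the smallest DSA among its
# 11 slices (narrowest-slice rule).

#' Dural-sac area from a binary mask
#'
#' Area = number of positive pixels times the pixel area.
#'
#' @param mask binary 2D matrix (0/1 or logical).
#' @param pixel_spacing_mm in-plane pixel spacing, scalar (square pixels) or
#'   length 2 (x, y).
#' @return Area in mm2.
#' @export
dsa_from_mask <- function(mask, pixel_spacing_mm) {
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (0/1)")
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be positive")
  px <- if (length(pixel_spacing_mm) == 1)
    pixel_spacing_mm^2 else pixel_spacing_mm[1] * pixel_spacing_mm[2]
  sum(mask == 1) * px
}

#' Dichotomous stenosis classification
#'
#' Normal when DSA >= 100 mm2, stenosis when < 100 mm2.
#' @param dsa_mm2 dural-sac area(s), mm2, non-negative.
#' @return Factor with levels \code{normal}, \code{stenosis}.
#' @export
classify_dichotomous <- function(dsa_mm2) {
  if (any(dsa_mm2 < 0)) stop("DSA must be non-negative")
  factor(ifelse(dsa_mm2 >= STENOSIS_THRESHOLD_MM2, "normal", "stenosis"),
         levels = c("normal", "stenosis"))
}

#' Severe stenosis classification
#'
#' Normal when DSA >= 75 mm2, severe stenosis when < 75 mm2.
#' @inheritParams classify_dichotomous
#' @return Factor with levels \code{normal}, \code{severe_stenosis}.
#' @export
classify_severe <- function(dsa_mm2) {
  if (any(dsa_mm2 < 0)) stop("DSA must be non-negative")
  factor(ifelse(dsa_mm2 >= SEVERE_THRESHOLD_MM2, "normal", "severe_stenosis"),
         levels = c("normal", "severe_stenosis"))
}

#' Level summary under the narrowest-slice rule
#'
#' The smallest DSA among the 11 slices of a level represents the level;
#' both classifications are applied to that minimum.
#'
#' @param dsa_mm2 the 11 per-slice areas of one level.
#' @return List: \code{min_dsa_mm2}, \code{dichotomous}, \code{severe}, and
#'   the offset index of the minimum.
#' @export
level_summary <- function(dsa_mm2) {
  if (length(dsa_mm2) != 11)
    stop(sprintf("expected 11 slice measurements for the level, got %d",
                 length(dsa_mm2)))
  if (anyNA(dsa_mm2)) stop("missing slice measurements")
  m <- min(dsa_mm2)
  list(min_dsa_mm2 = m,
       dichotomous = classify_dichotomous(m),
       severe = classify_severe(m),
       argmin = as.integer(which.min(dsa_mm2)))
}

#' Per-level DSA table from slice measurements
#'
#' Aggregates a slice-level measurement table (one row per slice) into one
#' row per (patient, mode, level) with the narrowest-slice DSA and both
#' classifications.
#'
#' @param measurements data.frame with columns patient_id, mode, level,
#'   offset_mm, dsa_mm2.
#' @return data.frame with min_dsa_mm2, dichotomous, severe per level.
#' @export
summarize_levels <- function(measurements) {
  sp <- split(measurements,
              interaction(measurements$patient_id, measurements$mode,
                          measurements$level, drop = TRUE))
  out <- do.call(rbind, lapply(sp, function(d) {
    ls <- level_summary(d$dsa_mm2)
    data.frame(patient_id = d$patient_id[1], mode = d$mode[1],
               level = d$level[1], min_dsa_mm2 = ls$min_dsa_mm2,
               dichotomous = as.character(ls$dichotomous),
               severe = as.character(ls$severe))
  }))
  rownames(out) <- NULL
  out[order(out$patient_id, out$mode, out$level), ]
}
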