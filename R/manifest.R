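# Dataset manifest construction, reproducing the clinical study's sampling
# arithmetic: development patients carry exactly one randomly assigned
# labeled disc level (the other four levels are unlabeled); test patients
# carry all five levels labeled.  Every (patient, modality, level) expands
# to 11 slices at offsets -5..+5 mm.

#' Build a dataset manifest
#'
#' @param patient_ids character vector of patient identifiers.
#' @param split_plan named counts, e.g. \code{c(train = 81, validation = 19,
#'   test = 9)}; must sum to \code{length(patient_ids)}.  Patients are
#'   assigned in order: training, validation, then test.
#' @param seed RNG seed for the per-patient labeled-level assignment.
#' @param modes acquisition modes available per patient.
#' @param levels disc level names.
#' @return A data.frame of class \code{dataset_manifest}, one row per slice:
#'   patient_id, mode, level, offset_mm, split, labeled, image, label.
#' @export
build_manifest <- function(patient_ids,
                           split_plan = c(train = 81, validation = 19, test = 9),
                           seed = 1,
                           modes = c("lumbar", "abdominal"),
                           levels = DISC_LEVELS) {
  if (sum(split_plan) != length(patient_ids))
    stop(sprintf("split plan sums to %d but %d patients were given",
                 sum(split_plan), length(patient_ids)))
  if (anyDuplicated(patient_ids)) stop("duplicated patient ids")
  split <- rep(names(split_plan), split_plan)
  dev <- split %in% c("train", "validation")
  labeled_level <- rep(NA_character_, length(patient_ids))
  labeled_level[dev] <- with_seed(seed,
    sample(levels, sum(dev), replace = TRUE))
  rows <- lapply(seq_along(patient_ids), function(i) {
    lab <- if (dev[i]) levels == labeled_level[i] else rep(TRUE, length(levels))
    expand.grid(patient_id = patient_ids[i], mode = modes, level = levels,
                offset_mm = SLICE_OFFSETS_MM, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE) |>
      transform(split = split[i],
                labeled = lab[match(level, levels)])
  })
  m <- do.call(rbind, rows)
  m$image <- sprintf("%s_%s_%s_%+03d.nii", m$patient_id, m$mode,
                     gsub("-", "", m$level), m$offset_mm)
  m$label <- ifelse(m$labeled, sprintf("%s_%s_%s_%+03d_label.nii",
                                       m$patient_id, m$mode,
                                       gsub("-", "", m$level), m$offset_mm),
                    NA_character_)
  rownames(m) <- NULL
  class(m) <- c("dataset_manifest", "data.frame")
  m
}

#' Summarize manifest counting identities
#'
#' @param manifest a [build_manifest()] result.
#' @return List with image counts by split, labeled image counts, and level
#'   counts for the test split by modality.
#' @export
manifest_counts <- function(manifest) {
  dev <- manifest[manifest$split %in% c("train", "validation"), ]
  test <- manifest[manifest$split == "test", ]
  tl <- unique(test[, c("patient_id", "mode", "level")])
  list(development_labeled_images = sum(dev$labeled),
       development_unlabeled_images = sum(!dev$labeled),
       test_images = nrow(test),
       test_levels = nrow(tl),
       test_levels_by_mode = table(tl$mode),
       labeled_levels_per_dev_patient =
         unique(as.vector(tapply(dev$labeled, dev$patient_id,
                                 function(x) sum(x) / (2 * 11)))))
}

#' Write / read a manifest as a delimited table
#' @param manifest a manifest data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or the manifest (read).
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  class(m) <- c("dataset_manifest", "data.frame")
  m
}
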