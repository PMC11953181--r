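# Agreement and diagnostic metrics: Dice similarity coefficient, two-way
# random-effects absolute-agreement single-measure ICC(2,1) with F-based
# 95% CI, exact (Clopper-Pearson) binomial CIs for accuracy / sensitivity /
# specificity, and the narrowest-slice clinical comparison.

#' Dice similarity coefficient
#'
#' \code{2|A n B| / (|A| + |B|)}; two empty masks are defined as identical
#' (DSC = 1), which avoids spurious failures on stenosis-free slices.
#'
#' @param mask_a,mask_b binary masks of identical shape.
#' @return Coefficient in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must have identical shape")
  a <- mask_a == 1; b <- mask_b == 1
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC with the
#' F-based 95% confidence interval, the standard form for method-agreement
#' studies.  Computed from the two-way ANOVA mean squares.
#'
#' @param x,y paired measurements (>= 3 pairs, finite).
#' @param conf confidence level.
#' @return List: \code{estimate}, \code{ci} (length 2), \code{n}.
#' @export
icc <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  if (var(rowMeans(m)) < .Machine$double.eps)
    stop("zero variance across subjects; ICC is undefined")
  MSR <- k * var(rowMeans(m))                       # between subjects
  MSC <- n * var(colMeans(m))                       # between raters
  MSE <- (sum((m - grand)^2) - (n - 1) * MSR - (k - 1) * MSC) /
    ((n - 1) * (k - 1))
  est <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  # F-based CI (Shrout & Fleiss case 2; McGraw & Wong A,1)
  alpha <- 1 - conf
  Fj <- MSC / MSE
  a <- k * est / (n * (1 - est))
  vn <- (k - 1) * (n - 1) * (k * est * Fj + n * (1 + (k - 1) * est) - k * est)^2
  vd <- (n - 1) * k^2 * est^2 * Fj^2 +
    (n * (1 + (k - 1) * est) - k * est)^2
  v <- vn / vd
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(estimate = est, ci = c(lower, upper), n = n)
}

#' Confusion counts
#'
#' Stenosis is the positive class throughout.
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A list of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

# exact binomial (Clopper-Pearson) CI as proportions
clopper_pearson <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

#' Accuracy, sensitivity and specificity with exact 95% CIs
#'
#' Proportions are reported as percentages; confidence intervals use the
#' exact Clopper-Pearson binomial method.  A zero denominator yields NA for
#' that metric rather than an error.
#'
#' @param counts a [confusion_counts()].
#' @param conf confidence level.
#' @return data.frame with one row per metric: value (percent), CI bounds
#'   (percent), and the raw numerator/denominator.
#' @export
confusion_metrics <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  one <- function(metric, x, n) {
    if (n == 0)
      return(data.frame(metric = metric, percent = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        numerator = x, denominator = n))
    ci <- clopper_pearson(x, n, conf) * 100
    data.frame(metric = metric, percent = 100 * x / n,
               ci_lower = ci[1], ci_upper = ci[2],
               numerator = x, denominator = n)
  }
  with(counts, rbind(
    one("accuracy", tp + tn, tp + tn + fp + fn),
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp)))
}

#' Narrowest-slice comparison against a reader
#'
#' For each level, the algorithm's minimum DSA over all slices is compared
#' with the reader's DSA at the slice the reader chose as narrowest:
#' within \code{tolerance_mm2} the level counts as \code{equal}; an
#' algorithm minimum smaller than the reader's value counts as
#' \code{algorithm_narrower} (the algorithm found a narrower slice), larger
#' as \code{reader_narrower}.
#'
#' @param algorithm data.frame with columns level_id and dsa_mm2 (one row
#'   per slice).
#' @param reader data.frame with columns level_id and dsa_mm2 (one row per
#'   level).  Levels missing a reader measurement are skipped with a
#'   message.
#' @param tolerance_mm2 tie tolerance, mm2.
#' @return List: per-category counts, total, and the per-level table.
#' @export
narrowest_slice_comparison <- function(algorithm, reader, tolerance_mm2 = 1) {
  amin <- aggregate(dsa_mm2 ~ level_id, data = algorithm, FUN = min)
  names(amin)[2] <- "algorithm_min"
  skipped <- setdiff(amin$level_id, reader$level_id)
  if (length(skipped))
    message(length(skipped), " level(s) skipped: no reader measurement")
  tab <- merge(amin, reader[, c("level_id", "dsa_mm2")], by = "level_id")
  names(tab)[3] <- "reader_dsa"
  d <- tab$algorithm_min - tab$reader_dsa
  tab$category <- ifelse(abs(d) <= tolerance_mm2, "equal",
                         ifelse(d < 0, "algorithm_narrower", "reader_narrower"))
  counts <- c(equal = sum(tab$category == "equal"),
              algorithm_narrower = sum(tab$category == "algorithm_narrower"),
              reader_narrower = sum(tab$category == "reader_narrower"))
  list(counts = counts, total = nrow(tab), levels = tab,
       skipped = skipped, tolerance_mm2 = tolerance_mm2)
}

#' Evaluate predictions over a test set
#'
#' Computes the full report: per-stratum (overall, abdominal, lumbar) Dice
#' mean and sd, ICC between predicted and reference DSA, slice-level
#' accuracy / sensitivity / specificity at the 100 mm2 threshold, the
#' severe-stenosis analysis at 75 mm2, and level-level accuracy under the
#' narrowest-slice rule.
#'
#' @param predictions data.frame, one row per slice: patient_id, mode,
#'   level, offset_mm, dsa_mm2 (predicted), optionally dice.
#' @param truth data.frame with the same keys and reference dsa_mm2.
#' @return An object of class \code{eval_report}.
#' @export
evaluate_testset <- function(predictions, truth) {
  keys <- c("patient_id", "mode", "level", "offset_mm")
  tab <- merge(predictions, truth, by = keys, suffixes = c("_pred", "_ref"))
  if (nrow(tab) < nrow(truth)) {
    miss <- nrow(truth) - nrow(tab)
    stop("predictions do not cover the reference set: ", miss,
         " slice(s) missing")
  }
  strata <- list(overall = rep(TRUE, nrow(tab)),
                 abdominal = tab$mode == "abdominal",
                 lumbar = tab$mode == "lumbar")
  mkcounts <- function(pred_pos, ref_pos) {
    confusion_counts(tp = sum(pred_pos & ref_pos),
                     fp = sum(pred_pos & !ref_pos),
                     tn = sum(!pred_pos & !ref_pos),
                     fn = sum(!pred_pos & ref_pos))
  }
  rows <- lapply(names(strata), function(nm) {
    d <- tab[strata[[nm]], ]
    pred_pos <- d$dsa_mm2_pred < STENOSIS_THRESHOLD_MM2
    ref_pos <- d$dsa_mm2_ref < STENOSIS_THRESHOLD_MM2
    cm <- confusion_metrics(mkcounts(pred_pos, ref_pos))
    ic <- tryCatch(icc(d$dsa_mm2_pred, d$dsa_mm2_ref),
                   error = function(e) list(estimate = NA_real_,
                                            ci = c(NA_real_, NA_real_)))
    data.frame(stratum = nm, n_slices = nrow(d),
               dsc_mean = if ("dice" %in% names(predictions))
                 mean(d$dice) else NA_real_,
               dsc_sd = if ("dice" %in% names(predictions))
                 sd(d$dice) else NA_real_,
               icc = ic$estimate, icc_lower = ic$ci[1], icc_upper = ic$ci[2],
               accuracy = cm$percent[1], acc_lower = cm$ci_lower[1],
               acc_upper = cm$ci_upper[1],
               sensitivity = cm$percent[2], sens_lower = cm$ci_lower[2],
               sens_upper = cm$ci_upper[2],
               specificity = cm$percent[3], spec_lower = cm$ci_lower[3],
               spec_upper = cm$ci_upper[3])
  })
  # severe-threshold analysis over all slices
  pred_sev <- tab$dsa_mm2_pred < SEVERE_THRESHOLD_MM2
  ref_sev <- tab$dsa_mm2_ref < SEVERE_THRESHOLD_MM2
  cm_sev <- confusion_metrics(mkcounts(pred_sev, ref_sev))
  # level-level accuracy at the narrowest DSA
  lp <- summarize_levels(data.frame(patient_id = tab$patient_id,
                                    mode = tab$mode, level = tab$level,
                                    offset_mm = tab$offset_mm,
                                    dsa_mm2 = tab$dsa_mm2_pred))
  lr <- summarize_levels(data.frame(patient_id = tab$patient_id,
                                    mode = tab$mode, level = tab$level,
                                    offset_mm = tab$offset_mm,
                                    dsa_mm2 = tab$dsa_mm2_ref))
  lv <- merge(lp, lr, by = c("patient_id", "mode", "level"),
              suffixes = c("_pred", "_ref"))
  level_acc <- confusion_metrics(mkcounts(
    lv$dichotomous_pred == "stenosis", lv$dichotomous_ref == "stenosis"))
  structure(list(strata = do.call(rbind, rows),
                 severe = cm_sev,
                 level_accuracy = level_acc,
                 n_levels = nrow(lv),
                 ci_method = "Clopper-Pearson (exact binomial)",
                 icc_form = "ICC(2,1) two-way random, absolute agreement"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt_pct <- function(v, lo, hi, num = NA, den = NA) {
    raw <- if (!is.na(num)) sprintf(" [%d/%d]", num, den) else ""
    sprintf("%.1f%s (%.1f-%.1f)", v, raw, lo, hi)
  }
  cat("Segmentation and classification performance\n")
  cat(sprintf("CIs: %s; ICC form: %s\n\n", x$ci_method, x$icc_form))
  s <- x$strata
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-10s n=%d", s$stratum[i], s$n_slices[i]))
    if (!is.na(s$dsc_mean[i]))
      cat(sprintf("  DSC %.2f +- %.2f", s$dsc_mean[i], s$dsc_sd[i]))
    if (!is.na(s$icc[i]))
      cat(sprintf("  ICC %.2f (%.2f-%.2f)", s$icc[i], s$icc_lower[i],
                  s$icc_upper[i]))
    cat(sprintf("\n  accuracy %s  sensitivity %s  specificity %s\n",
                fmt_pct(s$accuracy[i], s$acc_lower[i], s$acc_upper[i]),
                fmt_pct(s$sensitivity[i], s$sens_lower[i], s$sens_upper[i]),
                fmt_pct(s$specificity[i], s$spec_lower[i], s$spec_upper[i])))
  }
  sv <- x$severe
  cat(sprintf("severe (75 mm2): accuracy %s  sensitivity %s  specificity %s\n",
              fmt_pct(sv$percent[1], sv$ci_lower[1], sv$ci_upper[1],
                      sv$numerator[1], sv$denominator[1]),
              fmt_pct(sv$percent[2], sv$ci_lower[2], sv$ci_upper[2],
                      sv$numerator[2], sv$denominator[2]),
              fmt_pct(sv$percent[3], sv$ci_lower[3], sv$ci_upper[3],
                      sv$numerator[3], sv$denominator[3])))
  la <- x$level_accuracy
  cat(sprintf("level-level (narrowest DSA, %d levels): accuracy %s\n",
              x$n_levels,
              fmt_pct(la$percent[1], la$ci_lower[1], la$ci_upper[1],
                      la$numerator[1], la$denominator[1])))
  invisible(x)
}
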