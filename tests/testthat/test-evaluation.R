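test_that("dice handles the canonical cases", {
  a <- matrix(0L, 10, 10); a[2:6, 2:6] <- 1L
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 10, 10); b[8:10, 8:10] <- 1L
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50 -> 0.5
  a2 <- matrix(0L, 20, 20); a2[1:10, 1:10] <- 1L
  b2 <- matrix(0L, 20, 20); b2[1:10, 6:15] <- 1L
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(b2, a2), 0.5)
  expect_equal(dice(matrix(0L, 5, 5), matrix(0L, 5, 5)), 1)
  expect_error(dice(a, matrix(0L, 5, 5)), "shape")
})

test_that("icc equals 1 for duplicated raters and matches the ANOVA oracle", {
  x <- c(100, 120, 95, 140, 110, 80)
  expect_equal(icc(x, x)$estimate, 1, tolerance = 1e-9)
  y <- c(102, 118, 99, 135, 115, 78)
  est <- icc(x, y)
  # independent oracle: two-way ANOVA mean squares computed by aov(),
  # plugged into the absolute-agreement single-measure formula
  d <- data.frame(val = c(x, y),
                  subj = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(val ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 6; k <- 2
  oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  expect_equal(est$estimate, oracle, tolerance = 1e-6)
  # cross-check against an independently computed reference value
  expect_equal(est$estimate, 0.984029484029484, tolerance = 1e-9)
  expect_true(est$ci[1] <= est$estimate && est$estimate <= est$ci[2])
  expect_equal(est$ci, c(0.89, 1.00), tolerance = 0.005)
})

test_that("a constant rater offset lowers absolute-agreement ICC", {
  x <- c(100, 120, 95, 140, 110, 80)
  y <- c(102, 118, 99, 135, 115, 78)
  base <- icc(x, y)$estimate
  shifted <- icc(x, y + 10)$estimate
  expect_lt(shifted, base)
  expect_equal(shifted, 0.870021723388849, tolerance = 1e-9)
})

test_that("degenerate icc input is signalled explicitly", {
  expect_error(icc(c(1, 2), c(1, 2)), "3 complete pairs")
  expect_error(icc(rep(5, 6), rep(5, 6)), "zero variance")
})

test_that("confusion metrics reproduce printed worked examples", {
  # overall: sensitivity 281/391, specificity 550/599
  cm <- confusion_metrics(confusion_counts(tp = 281, fp = 599 - 550,
                                           tn = 550, fn = 391 - 281))
  expect_equal(round(cm$percent[cm$metric == "sensitivity"], 1), 71.9)
  expect_equal(round(cm$percent[cm$metric == "specificity"], 1), 91.8)
  expect_equal(round(cm$percent[cm$metric == "accuracy"], 1), 83.9)
  # exact binomial CI for 281/391: (67.1, 76.3) to 0.1 percentage points
  sens <- cm[cm$metric == "sensitivity", ]
  expect_equal(sens$ci_lower, 67.1, tolerance = 0.1)
  expect_equal(sens$ci_upper, 76.3, tolerance = 0.1)
  # perfect classifier
  pc <- confusion_metrics(confusion_counts(10, 0, 10, 0))
  expect_equal(pc$percent, c(100, 100, 100))
  # zero denominator reported as NA, not an error
  z <- confusion_metrics(confusion_counts(0, 5, 5, 0))
  expect_true(is.na(z$percent[z$metric == "sensitivity"]))
})

test_that("narrowest-slice comparison categorizes levels correctly", {
  alg <- data.frame(level_id = rep(c("L1", "L2", "L3"), each = 11),
                    dsa_mm2 = c(100 + abs(-5:5), 80 + 2 * abs(-5:5),
                                120 + abs(-5:5)))
  reader <- data.frame(level_id = c("L1", "L2", "L3"),
                       dsa_mm2 = c(100.4, 90, 115))
  res <- narrowest_slice_comparison(alg, reader, tolerance_mm2 = 1)
  expect_equal(res$total, 3)
  expect_equal(sum(res$counts), res$total)
  expect_equal(unname(res$counts["equal"]), 1)             # L1: 100 vs 100.4
  expect_equal(unname(res$counts["algorithm_narrower"]), 1) # L2: 80 vs 90
  expect_equal(unname(res$counts["reader_narrower"]), 1)    # L3: 120 vs 115
  # missing reader level is skipped, not fatal
  expect_message(narrowest_slice_comparison(alg, reader[-2, ]), "skipped")
})

test_that("a perfect reader against a perfect algorithm gives all-equal", {
  ph <- default_phantom()
  prof <- ph$truth$dsa_profile
  alg <- data.frame(level_id = rep(rownames(prof), each = 11),
                    dsa_mm2 = as.vector(t(prof)))
  reader <- data.frame(level_id = rownames(prof),
                       dsa_mm2 = apply(prof, 1, min))
  res <- narrowest_slice_comparison(alg, reader)
  expect_equal(unname(res$counts["equal"]), nrow(reader))
})

test_that("evaluate_testset produces a coherent report on perfect input", {
  set.seed(3)
  grid <- expand.grid(patient_id = c("T1", "T2"),
                      mode = c("lumbar", "abdominal"),
                      level = DISC_LEVELS, offset_mm = -5:5,
                      stringsAsFactors = FALSE)
  base <- 60 + 70 * as.integer(factor(grid$level)) / 5 +
    2 * abs(grid$offset_mm)
  truth <- cbind(grid, dsa_mm2 = base)
  preds <- cbind(grid, dsa_mm2 = base, dice = 1)
  rep <- evaluate_testset(preds, truth)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$strata$accuracy, rep(100, 3))
  expect_equal(rep$strata$dsc_mean, rep(1, 3))
  expect_equal(rep$strata$icc[1], 1, tolerance = 1e-9)
  expect_equal(rep$level_accuracy$percent[1], 100)
  expect_equal(rep$n_levels, 2 * 2 * 5)
  expect_equal(rep$strata$n_slices[1], nrow(grid))
  # report renders with CI parentheses and raw-count brackets
  txt <- capture.output(print(rep))
  expect_true(any(grepl("\\[\\d+/\\d+\\]", txt)))
  expect_true(any(grepl("\\(\\d+\\.\\d-\\d+\\.\\d\\)", txt)))
  # coverage gaps are fatal
  expect_error(evaluate_testset(preds[-1, ], truth), "cover")
})
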