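test_that("the study's dataset arithmetic is reproduced exactly", {
  ids <- sprintf("P%03d", 1:109)
  m <- build_manifest(ids, c(train = 81, validation = 19, test = 9), seed = 7)
  ct <- manifest_counts(m)
  # 100 development patients x 2 CTs x 1 labeled level x 11 slices
  expect_equal(ct$development_labeled_images, 2200)
  # 9 test patients x 2 CTs x 5 levels x 11 slices
  expect_equal(ct$test_images, 990)
  # 90 test levels, 45 per modality
  expect_equal(ct$test_levels, 90)
  expect_equal(unname(as.vector(ct$test_levels_by_mode)), c(45, 45))
  # every development patient carries exactly one labeled level
  expect_equal(ct$labeled_levels_per_dev_patient, 1)
  # unlabeled pool: 4 levels x 2 CTs x 11 slices per development patient
  expect_equal(ct$development_unlabeled_images, 100 * 4 * 2 * 11)
})

test_that("the labeled-level assignment is seeded and level-balanced-ish", {
  ids <- sprintf("P%03d", 1:50)
  m1 <- build_manifest(ids, c(train = 40, validation = 5, test = 5), seed = 3)
  m2 <- build_manifest(ids, c(train = 40, validation = 5, test = 5), seed = 3)
  expect_identical(m1, m2)
  lv <- unique(m1[m1$labeled & m1$split == "train",
                  c("patient_id", "level")])
  expect_gt(length(unique(lv$level)), 1)
})

test_that("inconsistent split plans are rejected", {
  expect_error(build_manifest(sprintf("P%d", 1:10),
                              c(train = 5, validation = 2, test = 2)),
               "sums to 9")
  expect_error(build_manifest(c("A", "A", "B"),
                              c(train = 2, validation = 0, test = 1)),
               "duplicated")
})

test_that("manifests round-trip through CSV", {
  ids <- sprintf("P%03d", 1:6)
  m <- build_manifest(ids, c(train = 3, validation = 2, test = 1), seed = 1)
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$labeled, m$labeled)
})
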