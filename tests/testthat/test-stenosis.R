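test_that("mask area is pixel count times pixel area", {
  expect_equal(dsa_from_mask(matrix(0L, 10, 10), 0.5), 0)
  m <- matrix(0L, 40, 40); m[1:20, 1:20] <- 1L  # 400 positive pixels
  expect_equal(dsa_from_mask(m, 0.5), 100)
  expect_equal(dsa_from_mask(m, c(0.5, 1)), 200)
  expect_error(dsa_from_mask(matrix(2L, 4, 4), 0.5), "binary")
  expect_error(dsa_from_mask(m, 0), "positive")
})

test_that("disk area is resolution-consistent", {
  disk_area <- function(px, r = 6) {
    n <- round(30 / px)
    x <- ((seq_len(n)) - 1 - n / 2) * px
    m <- outer(x, x, function(u, v) (u^2 + v^2 <= r^2) * 1L)
    dsa_from_mask(m, px)
  }
  a1 <- disk_area(0.5); a2 <- disk_area(0.25)
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("classification thresholds follow the clinical boundaries", {
  expect_equal(as.character(classify_dichotomous(100)), "normal")
  expect_equal(as.character(classify_dichotomous(99.99)), "stenosis")
  expect_equal(as.character(classify_dichotomous(127.6)), "normal")
  expect_equal(as.character(classify_dichotomous(50.6)), "stenosis")
  expect_equal(as.character(classify_severe(75)), "normal")
  expect_equal(as.character(classify_severe(74.99)), "severe_stenosis")
  expect_equal(as.character(classify_severe(50.6)), "severe_stenosis")
  # threshold ordering: 90 is stenosis but not severe
  expect_equal(as.character(classify_dichotomous(90)), "stenosis")
  expect_equal(as.character(classify_severe(90)), "normal")
  expect_error(classify_dichotomous(-1), "non-negative")
  expect_error(classify_severe(-0.1), "non-negative")
})

test_that("severe stenosis always implies dichotomous stenosis", {
  d <- c(0, 10, 74.99, 75, 99.99, 100, 150, runif(50, 0, 200))
  sev <- classify_severe(d) == "severe_stenosis"
  dic <- classify_dichotomous(d) == "stenosis"
  expect_true(all(!sev | dic))
})

test_that("the narrowest-slice rule takes the minimum of 11 slices", {
  expect_equal(level_summary(rep(120, 11))$min_dsa_mm2, 120)
  expect_equal(as.character(level_summary(rep(120, 11))$dichotomous),
               "normal")
  v <- c(110, 108, 106, 104, 102, 95, 102, 104, 106, 108, 110)
  ls <- level_summary(v)
  expect_equal(ls$min_dsa_mm2, 95)
  expect_equal(as.character(ls$dichotomous), "stenosis")
  expect_equal(ls$argmin, 6L)
  # order invariance of the minimum
  set.seed(1)
  expect_equal(level_summary(sample(v))$min_dsa_mm2, 95)
  expect_error(level_summary(v[-1]), "11")
})

test_that("the phantom taper makes the disc-centre slice the level minimum", {
  ph <- default_phantom()
  for (l in 1:5) {
    prof <- ph$truth$dsa_profile[l, ]
    ls <- level_summary(prof)
    expect_equal(ls$argmin, 6L)  # offset 0 = disc centre
    expect_equal(ls$min_dsa_mm2,
                 unname(ph$truth$config$level_dsa_mm2[l]))
  }
})

test_that("lowering any slice DSA can only push a level towards stenosis", {
  v <- c(110, 108, 106, 104, 102, 101, 102, 104, 106, 108, 110)
  before <- level_summary(v)$dichotomous
  expect_equal(as.character(before), "normal")
  for (i in c(1, 6, 11)) {
    w <- v; w[i] <- 60
    expect_equal(as.character(level_summary(w)$dichotomous), "stenosis")
  }
})
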