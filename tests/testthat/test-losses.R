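test_that("supervised loss has the expected closed forms", {
  mask <- matrix(0L, 8, 8); mask[3:5, 3:5] <- 1L
  # perfect one-hot prediction: loss bounded by the clamping constant
  perfect <- array(0, c(8, 8, 2))
  perfect[, , 1] <- 1 - mask; perfect[, , 2] <- mask
  expect_lt(supervised_loss(list(A = perfect, B = perfect), mask), 1e-6)
  # uniform prediction: pixel-averaged CE = ln 2 per decoder
  unif <- array(0.5, c(8, 8, 2))
  expect_equal(supervised_loss(list(A = unif, B = unif), mask) / 2, log(2),
               tolerance = 1e-6)
  # permutation invariance: shuffling pixels leaves the loss unchanged
  p <- array(runif(8 * 8 * 2), c(8, 8, 2))
  p2 <- sweep(p, c(1, 2), apply(p, c(1, 2), sum), "/")
  l1 <- supervised_loss(list(A = p2, B = p2), mask)
  idx <- sample(64)
  shuf <- function(a) array(c(matrix(a[, , 1], 64)[idx],
                              matrix(a[, , 2], 64)[idx]), c(8, 8, 2))
  mshuf <- matrix(as.integer(matrix(mask, 64)[idx]), 8, 8)
  expect_equal(supervised_loss(list(A = shuf(p2), B = shuf(p2)), mshuf), l1)
})

test_that("labels outside {0,1} are rejected", {
  unif <- array(0.5, c(4, 4, 2))
  bad <- matrix(2L, 4, 4)
  expect_error(supervised_loss(list(A = unif, B = unif), bad), "classes")
})

test_that("consistency loss is an L2 distance with channel-sum reduction", {
  pa <- array(0, c(2, 2, 2)); pa[, , 1] <- 1
  pb <- array(0, c(2, 2, 2)); pb[, , 2] <- 1
  expect_equal(consistency_loss(pa, pa), 0)
  # opposite one-hot maps: squared difference 1 per class channel -> 2
  expect_equal(consistency_loss(pa, pb), 2)
  p1 <- array(runif(32), c(4, 4, 2)); p2 <- array(runif(32), c(4, 4, 2))
  expect_equal(consistency_loss(p1, p2), consistency_loss(p2, p1))
  expect_error(consistency_loss(pa, array(0, c(3, 2, 2))), "shape")
})

test_that("the compiled step reports the same losses as the R reference", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 5))
  img <- matrix(rnorm(32 * 32), 32, 32)
  uimg <- matrix(rnorm(32 * 32), 32, 32)
  mask <- matrix(0L, 32, 32); mask[10:20, 10:20] <- 1L
  out_l <- forward(m, list(img, uimg), phase = "train")
  sup_ref <- supervised_loss(list(A = out_l[[1]]$A, B = out_l[[1]]$B), mask)
  cons_ref <- consistency_loss(out_l[[2]]$A, out_l[[2]]$B)
  st <- duralseg:::nn_train_step(m$ptr, list(img), list(as.integer(mask)),
                                 list(uimg), 1, 1e-3, 0.9, 0.999, 1e-8)
  expect_equal(st$supervised, sup_ref, tolerance = 1e-4)
  expect_equal(st$consistency, cons_ref, tolerance = 1e-4)
})
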