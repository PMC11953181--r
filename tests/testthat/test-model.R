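test_that("config validation catches impossible sizes", {
  expect_error(unet_config(input_size = c(100, 100), depth = 4),
               "divisible")
  expect_silent(unet_config(input_size = c(48, 48), depth = 4))
})

test_that("both decoders produce input-sized probability maps", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 2))
  img <- matrix(rnorm(32 * 32), 32, 32)
  out <- forward(m, img, phase = "train")
  expect_equal(dim(out$A), c(32, 32, 2))
  expect_equal(dim(out$B), c(32, 32, 2))
  sums <- apply(out$A, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("inference uses exactly one decoder", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 2))
  img <- matrix(rnorm(32 * 32), 32, 32)
  out <- forward(m, img, phase = "inference")
  expect_true(is.array(out))
  expect_equal(dim(out), c(32, 32, 2))
})

test_that("decoders hold disjoint parameters behind a shared encoder", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 2))
  nm <- names(model_params(m))
  a <- grep("^decA", nm, value = TRUE)
  b <- grep("^decB", nm, value = TRUE)
  enc <- grep("^(enc|bottleneck)", nm, value = TRUE)
  expect_gt(length(a), 0)
  expect_equal(length(a), length(b))
  expect_gt(length(enc), 0)
  expect_length(intersect(sub("^decA", "", a), sub("^decB", "", b)),
                length(a))  # same structure, different parameter sets
})

test_that("initialization is a pure function of the seed", {
  cfg <- unet_config(input_size = c(32, 32), depth = 3, base_channels = 4,
                     seed = 11)
  expect_identical(model_params(build_model(cfg)),
                   model_params(build_model(cfg)))
  cfg2 <- unet_config(input_size = c(32, 32), depth = 3, base_channels = 4,
                      seed = 12)
  expect_false(identical(model_params(build_model(cfg)),
                         model_params(build_model(cfg2))))
})

test_that("a constant-zero image yields finite probabilities", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 1))
  out <- forward(m, matrix(0, 32, 32), phase = "train")
  expect_true(all(is.finite(out$A)))
  expect_true(all(is.finite(out$B)))
})

test_that("shape mismatches are rejected", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 1))
  expect_error(forward(m, matrix(0, 16, 16)), "expects 32x32")
})

test_that("checkpoints round-trip through save/load", {
  m <- build_model(unet_config(input_size = c(32, 32), depth = 3,
                               base_channels = 4, seed = 3))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(model_params(m), model_params(m2))
  img <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(forward(m, img), forward(m2, img))
})
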