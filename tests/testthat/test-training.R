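test_that("with no unlabeled data the consistency component stays zero", {
  sl <- tiny_slices()[1:6]
  labeled <- lapply(sl, function(s) s[c("image", "mask")])
  m <- build_model(unet_config(input_size = c(64, 64), base_channels = 4,
                               seed = 1))
  fit <- train_model(m, labeled, list(),
                     training_config(epochs = 2, lambda = 0,
                                     augment = augment_identity(), seed = 1))
  expect_true(all(fit$history$consistency == 0))
  expect_equal(nrow(fit$history), 2)
})

test_that("an empty labeled set is rejected", {
  m <- build_model(unet_config(input_size = c(64, 64), base_channels = 4,
                               seed = 1))
  expect_error(train_model(m, list(), list(), training_config(epochs = 1)),
               "labeled")
})

test_that("the model memorizes a 4-slice task with non-increasing loss", {
  sl <- tiny_slices()[c(6, 17, 28, 39)]  # disc-centre slices, varied levels
  labeled <- lapply(sl, function(s) s[c("image", "mask")])
  m <- build_model(unet_config(input_size = c(64, 64), seed = 4))
  fit <- train_model(m, labeled, list(),
                     training_config(epochs = 25, batch_size = 4,
                                     augment = augment_identity(), seed = 4))
  l <- fit$history$supervised
  expect_lt(l[25], 0.5 * l[1])
  # trend is non-increasing (tiny optimizer wiggles tolerated)
  expect_true(all(diff(l) < 0.02))
  # the memorized slices are segmented nearly perfectly
  expect_gt(evaluate_dsc(fit$model, sl), 0.85)
})

test_that("identical seed, config and data reproduce identical training", {
  sl <- tiny_slices()[1:8]
  labeled <- lapply(sl[1:4], function(s) s[c("image", "mask")])
  unlabeled <- lapply(sl[5:8], function(s) s$image)
  run <- function() {
    m <- build_model(unet_config(input_size = c(64, 64), base_channels = 4,
                                 seed = 2))
    train_model(m, labeled, unlabeled,
                training_config(epochs = 2, seed = 9))$history
  }
  expect_identical(run(), run())
})
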