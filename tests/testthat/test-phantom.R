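test_that("phantom generation is deterministic and labels are well-formed", {
  cfg <- phantom_config()
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$volume$intensities, ph2$volume$intensities)
  expect_identical(ph1$label$classes, ph2$label$classes)
  # every voxel carries exactly one class from the enumerated set
  expect_true(all(ph1$label$classes %in% 0:4))
  expect_true(all(table(ph1$label$classes)[-1] > 0))
})

test_that("zero curvature gives collinear centroids along z", {
  ph <- straight_phantom()
  cent <- ph$truth$centroids_mm
  expect_equal(diff(range(cent[, 1])), 0)
  expect_equal(diff(range(cent[, 2])), 0)
  expect_true(all(diff(cent[, 3]) > 0))
})

test_that("true dural-sac area at each disc centre recovers the target", {
  areas <- c("L1-L2" = 50, "L2-L3" = 75, "L3-L4" = 100, "L4-L5" = 130,
             "L5-S1" = 95)
  cfg <- phantom_config(level_dsa_mm2 = areas)
  ph <- generate_phantom(cfg)
  cs <- duralseg:::phantom_curve_samples(cfg)
  for (l in seq_along(areas)) {
    i <- which.min(abs(cs$s - ph$truth$s_disc[l]))
    pl <- sampling_plane(cs$pts[i, ], cs$e1[i, ], cs$e2[i, ])
    a <- true_dsa(ph$label, pl, pixel_mm = 0.5)
    expect_lt(abs(a - areas[l]) / areas[l], 0.05)
  }
})

test_that("the analytic DSA profile is narrowest at the disc centre", {
  ph <- default_phantom()
  prof <- ph$truth$dsa_profile
  expect_equal(dim(prof), c(5L, 11L))
  for (l in 1:5) {
    expect_equal(unname(which.min(prof[l, ])), 6L)  # offset 0
    expect_equal(unname(prof[l, 6]),
                 unname(ph$truth$config$level_dsa_mm2[l]))
  }
})

test_that("true_dsa handles degenerate planes and simple shapes", {
  ph <- straight_phantom()
  # plane far outside the dural sac
  pl <- sampling_plane(c(5, 5, 2), c(1, 0, 0), c(0, 1, 0))
  expect_equal(true_dsa(ph$label, pl, fov_mm = 8), 0)
  # a 10x10-pixel square sac at 0.5 mm pixels -> 25 mm2
  lab <- array(0L, c(32, 32, 8))
  lab[11:20, 11:20, 4] <- 2L
  lv <- label_volume(lab, c(0.5, 0.5, 1.0))
  pl <- sampling_plane(c(7.5, 7.5, 3), c(1, 0, 0), c(0, 1, 0))
  expect_equal(true_dsa(lv, pl, fov_mm = 16, pixel_mm = 0.5), 25)
})

test_that("an analytic ellipse recovers pi*a*b", {
  # semi-axes (7, 5) mm -> 109.956 mm2
  lab <- array(0L, c(64, 64, 8))
  x <- ((0:63) - 32) * 0.5
  m <- outer(x, x, function(u, v) (u / 7)^2 + (v / 5)^2 <= 1)
  for (k in 3:6) lab[, , k][m] <- 2L
  lv <- label_volume(lab, c(0.5, 0.5, 1.0))
  pl <- sampling_plane(c(16, 16, 4), c(1, 0, 0), c(0, 1, 0))
  a <- true_dsa(lv, pl, fov_mm = 30, pixel_mm = 0.5)
  expect_lt(abs(a - pi * 7 * 5) / (pi * 7 * 5), 0.03)
})

test_that("acquisition modes behave as specified", {
  ph <- straight_phantom()
  lum <- apply_acquisition_mode(ph$volume, ph$label, "lumbar",
                                noise_sd_hu = 0)
  expect_identical(lum$intensities, ph$volume$intensities)
  expect_equal(lum$spacing[3], 1)
  abd <- apply_acquisition_mode(ph$volume, ph$label, "abdominal",
                                noise_sd_hu = 0)
  expect_equal(abd$spacing[3], 2)
  # contrast raises ligamentum flavum attenuation relative to lumbar mode
  lig <- ph$label$classes == label_codes()[["ligamentum_flavum"]]
  lig2 <- lig[, , 2 * seq_len(dim(abd$intensities)[3])]
  expect_gt(mean(abd$intensities[lig2]), mean(lum$intensities[lig]))
  expect_error(apply_acquisition_mode(ph$volume, ph$label, "axial"))
  # noise is seeded
  n1 <- apply_acquisition_mode(ph$volume, ph$label, "lumbar",
                               noise_sd_hu = 5, seed = 9)
  n2 <- apply_acquisition_mode(ph$volume, ph$label, "lumbar",
                               noise_sd_hu = 5, seed = 9)
  expect_identical(n1$intensities, n2$intensities)
})

test_that("impossible sac geometry is rejected", {
  expect_error(phantom_config(level_dsa_mm2 = c("L1-L2" = 400, "L2-L3" = 100,
                                                "L3-L4" = 100, "L4-L5" = 100,
                                                "L5-S1" = 100)),
               "fit")
  expect_error(phantom_config(n_vertebrae = 1), "n_vertebrae")
  expect_error(phantom_config(voxel_spacing_mm = c(0.5, -1, 1)))
})
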