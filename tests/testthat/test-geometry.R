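test_that("centroids are found on straight and curved phantoms", {
  vol <- straight_volume()
  cent <- locate_centroids(vol)
  expect_equal(nrow(cent), 6)
  expect_equal(diff(range(cent[, 1])), 0, tolerance = 1e-6)
  expect_equal(diff(range(cent[, 2])), 0, tolerance = 1e-6)
  ph <- default_phantom()
  volc <- apply_acquisition_mode(ph$volume, ph$label, "lumbar",
                                 noise_sd_hu = 10, seed = 2)
  centc <- locate_centroids(volc)
  err <- sqrt(rowSums((centc - ph$truth$centroids_mm)^2))
  expect_lt(max(err), 2)
})

test_that("an all-background volume is rejected", {
  empty <- ct_volume(array(-100, c(16, 16, 16)), c(1, 1, 1))
  expect_error(locate_centroids(empty), "bone")
})

test_that("two collinear centroids give a straight constant-tangent curve", {
  cent <- rbind(c(10, 10, 0), c(10, 10, 50))
  cv <- fit_spinal_curve(cent)
  expect_equal(cv$pos(0), matrix(cent[1, ], 1), tolerance = 1e-8,
               ignore_attr = TRUE)
  tt <- cv$tan(c(0, 10, 25, 49))
  expect_equal(tt, matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE),
               tolerance = 1e-8)
  expect_equal(cv$length, 50, tolerance = 0.01)
})

test_that("a circular arc is interpolated to sub-millimetre accuracy", {
  # centroids on a circle of radius 100 in the x-z plane
  th <- seq(-0.3, 0.3, length.out = 7)
  cent <- cbind(100 * cos(th) - 100, 20, 100 * sin(th) + 60)
  cv <- fit_spinal_curve(cent)
  # arc midpoint = point at half total arc length; circle is symmetric so
  # it is the centroid at theta = 0
  mid <- cv$pos(cv$length / 2)
  expect_lt(sqrt(sum((mid - c(0, 20, 60))^2)), 0.5)
  # arc-length parameterization: total length ~ r * dtheta
  expect_equal(cv$length, 100 * 0.6, tolerance = 0.1)
})

test_that("degenerate centroid input is rejected", {
  expect_error(fit_spinal_curve(rbind(c(0, 0, 5))), "2 centroids")
  expect_error(fit_spinal_curve(rbind(c(0, 0, 5), c(0, 0, 5))), "increasing z")
  expect_error(fit_spinal_curve(rbind(c(0, 0, 5), c(0, 0, 9), c(0, 0, 7))))
})

test_that("disc centres sit at arc-length midpoints", {
  ph <- default_phantom()
  volc <- apply_acquisition_mode(ph$volume, ph$label, "lumbar",
                                 noise_sd_hu = 5, seed = 3)
  cv <- fit_spinal_curve(locate_centroids(volc))
  dc <- disc_centers(cv)
  expect_equal(nrow(dc), 5)
  err <- sqrt(rowSums((dc - ph$truth$disc_centers_mm)^2))
  expect_lt(max(err), 1.5)
  # straight equally spaced spine: Euclidean midpoints
  cent <- cbind(10, 20, seq(0, 100, by = 20))
  dcs <- disc_centers(fit_spinal_curve(cent))
  expect_equal(dcs[, 3], seq(10, 90, by = 20), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("reformatting a straight spine on the native grid is the identity", {
  vol <- straight_volume()
  cv <- fit_spinal_curve(locate_centroids(vol))
  dc <- disc_centers(cv)
  s_dc <- attr(dc, "s")
  st <- reformat_level(vol, cv, s_dc[3], fov_mm = 48, pixel_mm = 0.5)
  expect_equal(dim(st$slices), c(96, 96, 11))
  # native axial indices covered by the reformat grid
  n <- 96
  ix <- round(((0:(n - 1) - n %/% 2) * 0.5 + dc[3, 1]) / 0.5) + 1
  rng <- diff(range(vol$intensities))
  for (k in c(1, 6, 11)) {
    z <- dc[3, 3] + st$offsets_mm[k]
    native <- vol$intensities[ix, ix, round(z) + 1]
    expect_lt(max(abs(st$slices[, , k] - native)), 1e-4 * rng)
  }
})

test_that("slice planes are orthonormal with normal equal to the tangent", {
  ph <- default_phantom()
  volc <- apply_acquisition_mode(ph$volume, ph$label, "lumbar",
                                 noise_sd_hu = 0)
  cv <- fit_spinal_curve(locate_centroids(volc))
  s_dc <- attr(disc_centers(cv), "s")
  st <- reformat_level(volc, cv, s_dc[2], fov_mm = 40, pixel_mm = 0.5)
  expect_length(st$frames, 11)
  for (f in st$frames) {
    expect_equal(sum(f$e1^2), 1, tolerance = 1e-9)
    expect_equal(sum(f$e2^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(f$e1 * f$e2)), 1e-9)
    tn <- cv$tan(f$s)
    expect_lt(max(abs(duralseg:::cross3(f$e1, f$e2) - tn)), 1e-6)
  }
})

test_that("a 30-degree cylinder yields the perpendicular section, not the axial one", {
  cyl <- make_cylinder()
  true_area <- pi * cyl$r^2
  # native axial section is stretched by 1/cos(theta)
  k <- round(cyl$center[3] / 0.5) + 1
  axial <- sum(cyl$label$classes[, , k] == 2L) * 0.25
  expect_equal(axial, true_area / cos(cyl$theta), tolerance = 0.03)
  # reformat along the cylinder axis: perpendicular section ~ pi r^2
  c1 <- cyl$center - 20 * cyl$axis
  c2 <- cyl$center + 20 * cyl$axis
  cv <- fit_spinal_curve(rbind(c1, c2))
  st <- reformat_level(cyl$volume, cv, 20, label = cyl$label,
                       fov_mm = 40, pixel_mm = 0.25)
  perp <- sum(st$label_slices[, , 6] == 2L) * 0.0625
  expect_lt(abs(perp - true_area) / true_area, 0.03)
})

test_that("reformatted area is resolution-consistent", {
  cyl <- make_cylinder()
  c1 <- cyl$center - 20 * cyl$axis
  c2 <- cyl$center + 20 * cyl$axis
  cv <- fit_spinal_curve(rbind(c1, c2))
  a <- vapply(c(0.5, 0.25), function(px) {
    st <- reformat_level(cyl$volume, cv, 20, label = cyl$label,
                         fov_mm = 40, pixel_mm = px)
    sum(st$label_slices[, , 6] == 2L) * px^2
  }, numeric(1))
  expect_lt(abs(a[2] - a[1]) / a[1], 0.02)
})

test_that("a stack reaching outside the volume names the offending offset", {
  vol <- straight_volume()
  cv <- fit_spinal_curve(locate_centroids(vol))
  expect_error(reformat_level(vol, cv, cv$length + 3), "offset")
})
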