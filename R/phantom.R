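# Synthetic spine-CT phantom: a stack of vertebral bodies along a smooth
# spinal curve, with an elliptical dural-sac tube whose cross-sectional area
# (in the plane perpendicular to the local curve tangent) is known
# analytically at every arc position.  The disc-centre slice of every level
# is the narrowest by construction (cosine taper over +-5 mm).

# fixed local-frame geometry of the phantom (mm); u = lateral, v = AP offset
# from the spinal curve.  Only relative contrasts matter downstream.
PHANTOM_GEOM <- list(
  body_a = 13,          # vertebral body lateral semi-axis
  body_b = 9,           # vertebral body AP semi-axis
  canal_v = -16,        # dural-sac centre, posterior of the curve
  lig_thick = 2,        # ligamentum flavum band thickness
  margin_depth = 4.5,   # max AP depth of the disc posterior margin band
  taper_halfwidth = 5   # cosine taper half-width around each disc centre
)

# pseudo-HU palette
PHANTOM_HU <- c(background = -30, bone = 700, disc = 60, margin = 60,
                ligament = 80, dural_sac = 15)
CONTRAST_OFFSET_HU <- 40

#' Phantom configuration
#'
#' Study-design quantities for the synthetic spine-CT generator.  Defaults
#' give a 6-vertebra lumbar stack whose five disc levels span the clinical
#' spectrum: normal (DSA >= 100 mm2), stenosis (< 100 mm2) and severe
#' stenosis (< 75 mm2).
#'
#' @param n_vertebrae number of vertebral bodies (>= 2).
#' @param vertebral_height_mm,disc_height_mm craniocaudal extents in mm.
#' @param curve_amplitude_mm lateral/AP deviation of the spinal axis; 0 gives
#'   a perfectly straight spine.
#' @param level_dsa_mm2 named vector, target dural-sac cross-sectional area
#'   (mm2) at each disc centre; names are disc levels.
#' @param ellipse_aspect dural-sac minor/major axis ratio in (0, 1].
#' @param voxel_spacing_mm voxel spacing (x, y, z) in mm.
#' @param dim_vox grid size in voxels.
#' @param mode acquisition mode the phantom is destined for.
#' @param noise_sd_hu attenuation-noise standard deviation used by
#'   [apply_acquisition_mode()].
#' @param seed RNG seed for acquisition noise.
#' @return A validated list of class \code{phantom_config}.
#' @export
phantom_config <- function(n_vertebrae = 6, vertebral_height_mm = 18,
                           disc_height_mm = 6, curve_amplitude_mm = 6,
                           level_dsa_mm2 = c("L1-L2" = 130, "L2-L3" = 110,
                                             "L3-L4" = 95, "L4-L5" = 70,
                                             "L5-S1" = 50),
                           ellipse_aspect = 0.7,
                           voxel_spacing_mm = c(0.5, 0.5, 1.0),
                           dim_vox = c(128, 128, 160),
                           mode = c("lumbar", "abdominal"),
                           noise_sd_hu = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_vertebrae >= 2, vertebral_height_mm > 0, disc_height_mm > 0,
            curve_amplitude_mm >= 0, all(level_dsa_mm2 > 0),
            ellipse_aspect > 0, ellipse_aspect <= 1,
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            length(dim_vox) == 3, all(dim_vox >= 8), noise_sd_hu >= 0)
  if (length(level_dsa_mm2) != n_vertebrae - 1)
    stop("level_dsa_mm2 must give one area per disc level (n_vertebrae - 1)")
  if (is.null(names(level_dsa_mm2)))
    names(level_dsa_mm2) <- DISC_LEVELS[seq_along(level_dsa_mm2)]
  cfg <- list(n_vertebrae = n_vertebrae,
              vertebral_height_mm = vertebral_height_mm,
              disc_height_mm = disc_height_mm,
              curve_amplitude_mm = curve_amplitude_mm,
              level_dsa_mm2 = level_dsa_mm2,
              ellipse_aspect = ellipse_aspect,
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              dim_vox = as.integer(dim_vox), mode = mode,
              noise_sd_hu = noise_sd_hu, seed = seed)
  class(cfg) <- "phantom_config"
  # the widest sac (the inter-level baseline) must fit inside the canal
  g <- PHANTOM_GEOM
  A0 <- phantom_baseline_area(cfg)
  b0 <- sqrt(A0 * ellipse_aspect / pi)
  if (g$canal_v + b0 > -g$body_b - 0.5)
    stop(sprintf(paste0("dural-sac ellipse does not fit inside the canal: ",
                        "baseline area %.1f mm2 reaches the vertebral body"),
                 A0))
  span <- n_vertebrae * vertebral_height_mm +
    (n_vertebrae - 1) * disc_height_mm
  if (span + 16 > (dim_vox[3] - 1) * voxel_spacing_mm[3])
    stop("vertebral stack does not fit in the volume z-extent")
  cfg
}

# canal area away from disc centres; a little above the widest level
phantom_baseline_area <- function(config) {
  max(135, max(config$level_dsa_mm2) + 5)
}

# analytic spinal curve of the phantom, as a function of z (mm)
phantom_curve_xy <- function(config, z) {
  d <- config$dim_vox; sp <- config$voxel_spacing_mm
  cx <- sp[1] * (d[1] %/% 2)
  cy <- sp[2] * (d[2] %/% 2)
  zc <- phantom_vertebra_centers_z(config)
  t <- (z - zc[1]) / max(zc[length(zc)] - zc[1], 1e-9)
  A <- config$curve_amplitude_mm
  cbind(cx + A * sin(pi * t), cy + 0.4 * A * sin(2 * pi * t))
}

phantom_vertebra_centers_z <- function(config) {
  vh <- config$vertebral_height_mm; dh <- config$disc_height_mm
  n <- config$n_vertebrae
  span <- n * vh + (n - 1) * dh
  zext <- (config$dim_vox[3] - 1) * config$voxel_spacing_mm[3]
  z0 <- floor((zext - span) / 2) + vh / 2
  z0 + (0:(n - 1)) * (vh + dh)
}

# finely sampled curve with arc length, tangents, and rotation-minimizing
# frames (e1 ~ lateral/u, e2 ~ AP/v)
phantom_curve_samples <- function(config, ds_mm = 0.25) {
  zext <- (config$dim_vox[3] - 1) * config$voxel_spacing_mm[3]
  z <- seq(0, zext, by = ds_mm)
  xy <- phantom_curve_xy(config, z)
  pts <- cbind(xy, z)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  # tangents by central differences
  tan <- rbind(pts[2, ] - pts[1, ],
               (pts[-(1:2), ] - pts[1:(nrow(pts) - 2), ]) / 2,
               pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
  tan <- tan / sqrt(rowSums(tan^2))
  fr <- propagate_frames(pts, tan)
  list(pts = pts, s = s, z = z, tan = tan, e1 = fr$e1, e2 = fr$e2)
}

# double-reflection rotation-minimizing frames; the initial first axis is the
# projection of world x onto the first normal plane
propagate_frames <- function(pts, tan) {
  n <- nrow(pts)
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  r <- c(1, 0, 0) - sum(c(1, 0, 0) * tan[1, ]) * tan[1, ]
  if (sqrt(sum(r^2)) < 1e-8) r <- c(0, 1, 0) - sum(c(0, 1, 0) * tan[1, ]) * tan[1, ]
  r <- r / sqrt(sum(r^2))
  e1[1, ] <- r
  e2[1, ] <- cross3(tan[1, ], r)
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-14) {
      e1[i + 1, ] <- e1[i, ]; e2[i + 1, ] <- e2[i, ]; next
    }
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tan[i, ] - (2 / c1) * sum(v1 * tan[i, ]) * v1
    v2 <- tan[i + 1, ] - tL
    c2 <- sum(v2^2)
    r2 <- if (c2 < 1e-14) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    e1[i + 1, ] <- r2 / sqrt(sum(r2^2))
    e2[i + 1, ] <- cross3(tan[i + 1, ], e1[i + 1, ])
  }
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dural-sac area (mm2) at arc positions `s`, given disc-centre arc positions
phantom_area_profile <- function(s, s_disc, level_dsa, A0,
                                 halfwidth = PHANTOM_GEOM$taper_halfwidth) {
  A <- rep(A0, length(s))
  for (l in seq_along(s_disc)) {
    d <- abs(s - s_disc[l])
    w <- d < halfwidth
    A[w] <- pmin(A[w], level_dsa[l] +
                   (A0 - level_dsa[l]) * (1 - cos(pi * d[w] / halfwidth)) / 2)
  }
  A
}

#' Generate a synthetic spine-CT phantom
#'
#' Builds the clean (noise-free, pre-acquisition) intensity volume, the label
#' volume, and the analytic ground truth.  Vertebral bodies are elliptical
#' cylinders stacked along a smooth spinal curve; between them sits a disc
#' whose posterior margin, together with a ligamentum-flavum band, bounds an
#' elliptical dural-sac tube.  The sac's cross-sectional area in the plane
#' perpendicular to the local curve tangent equals \code{level_dsa_mm2} at
#' each disc centre and tapers (cosine, +-5 mm) to the inter-level baseline,
#' so the disc-centre slice is the narrowest of its level by construction.
#'
#' @param config a [phantom_config()].
#' @return A list of class \code{spine_phantom} with elements
#'   \code{volume} ([ct_volume()], clean intensities), \code{label}
#'   ([label_volume()]), and \code{truth}: vertebral centroids (mm), disc
#'   centres (mm), their arc positions, and the analytic per-slice DSA
#'   profile (level x offset -5..+5 mm).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- PHANTOM_GEOM
  sp <- config$voxel_spacing_mm; d <- config$dim_vox
  cs <- phantom_curve_samples(config)
  zc <- phantom_vertebra_centers_z(config)
  vh <- config$vertebral_height_mm; dh <- config$disc_height_mm
  zd <- zc[-length(zc)] + (vh + dh) / 2  # disc centre z
  # arc positions of vertebra/disc centres (curve is a graph over z)
  s_of_z <- approxfun(cs$z, cs$s)
  s_disc <- s_of_z(zd)
  A0 <- phantom_baseline_area(config)
  area_s <- phantom_area_profile(cs$s, s_disc, config$level_dsa_mm2, A0)
  # structure membership along the curve, by z
  in_vert <- rep(FALSE, length(cs$z))
  for (l in seq_along(zc)) {
    w <- cs$z >= zc[l] - vh / 2 & cs$z <= zc[l] + vh / 2
    in_vert[w] <- TRUE
  }
  in_disc <- !in_vert & cs$z > zc[1] & cs$z < zc[length(zc)]
  regions <- cpp_phantom_regions(
    dim = d, spacing = sp, origin = c(0, 0, 0),
    cpts = cs$pts, ce1 = cs$e1, ce2 = cs$e2, area_s = area_s,
    in_vertebra = in_vert, in_disc = in_disc,
    body_a = g$body_a, body_b = g$body_b, canal_v = g$canal_v,
    aspect = config$ellipse_aspect, lig_thick = g$lig_thick,
    margin_anterior_v = -(g$body_b + g$margin_depth))
  hu <- PHANTOM_HU
  pal <- c(hu[["background"]], hu[["bone"]], hu[["dural_sac"]],
           hu[["margin"]], hu[["ligament"]], hu[["disc"]])
  intens <- array(pal[regions + 1L], dim = d)
  labels <- regions
  labels[labels == 5L] <- 0L  # disc body carries no label class
  vol <- ct_volume(intens, sp, mode = config$mode)
  lab <- label_volume(array(as.integer(labels), dim = d), sp)
  # analytic ground truth
  cent_xy <- phantom_curve_xy(config, zc)
  disc_xy <- phantom_curve_xy(config, zd)
  prof <- outer(seq_along(s_disc), SLICE_OFFSETS_MM, function(l, o)
    phantom_area_profile(s_disc[l] + o, s_disc, config$level_dsa_mm2, A0))
  dimnames(prof) <- list(names(config$level_dsa_mm2),
                         as.character(SLICE_OFFSETS_MM))
  truth <- list(centroids_mm = cbind(cent_xy, zc),
                disc_centers_mm = cbind(disc_xy, zd),
                s_disc = s_disc,
                dsa_profile = prof,
                regions = regions,
                config = config)
  structure(list(volume = vol, label = lab, truth = truth),
            class = "spine_phantom")
}

#' Apply an acquisition mode to a phantom volume
#'
#' Emulates the two CT protocols.  Abdominal mode adds a contrast-agent
#' offset to soft tissue (disc and ligamentum flavum attenuation is raised
#' relative to the dural sac) and resamples the slice thickness to 2 mm by
#' partial-volume averaging of adjacent 1-mm slices; lumbar mode keeps 1-mm
#' slices without contrast.  Both add Gaussian attenuation noise.
#'
#' @param volume clean [ct_volume()] from [generate_phantom()].
#' @param label matching [label_volume()].
#' @param mode \code{"lumbar"} or \code{"abdominal"}.
#' @param noise_sd_hu noise standard deviation (HU); 0 disables noise.
#' @param seed RNG seed for the noise.
#' @return A new [ct_volume()]; the label volume is unchanged (it stays on
#'   the native 1-mm grid; reformatting works in world coordinates).
#' @export
apply_acquisition_mode <- function(volume, label, mode, noise_sd_hu = 10,
                                   seed = 1) {
  stopifnot(inherits(volume, "ct_volume"), inherits(label, "label_volume"))
  if (!identical(dim(volume$intensities), dim(label$classes)))
    stop("volume and label grids are not aligned")
  mode <- match.arg(mode, c("lumbar", "abdominal"))
  x <- volume$intensities
  spacing <- volume$spacing
  origin <- volume$origin
  if (mode == "abdominal") {
    soft <- label$classes == 3L | label$classes == 4L |
      abs(x - PHANTOM_HU[["disc"]]) < 0.5
    x[soft] <- x[soft] + CONTRAST_OFFSET_HU
    nz <- dim(x)[3] %/% 2L
    x <- (x[, , 2 * seq_len(nz) - 1, drop = FALSE] +
            x[, , 2 * seq_len(nz), drop = FALSE]) / 2
    origin[3] <- origin[3] + spacing[3] / 2
    spacing[3] <- 2 * spacing[3]
  }
  if (noise_sd_hu > 0)
    x <- x + array(with_seed(seed, rnorm(length(x), 0, noise_sd_hu)), dim(x))
  ct_volume(x, spacing, origin, mode = mode, patient_id = volume$patient_id)
}

#' Oblique plane through a volume
#'
#' Helper constructing the sampling frame used by [true_dsa()] and
#' [reformat_level()]: an origin plus two orthonormal in-plane axes.
#'
#' @param origin plane centre, world mm.
#' @param e1,e2 in-plane unit vectors (orthogonalized internally).
#' @return A list of class \code{sampling_plane}.
#' @export
sampling_plane <- function(origin, e1, e2) {
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  structure(list(origin = origin, e1 = e1, e2 = e2), class = "sampling_plane")
}

#' Ground-truth dural-sac area on an arbitrary plane
#'
#' Resamples the label volume on the plane (nearest-neighbour) and returns
#' the count of dural-sac pixels times the pixel area.  An empty intersection
#' gives 0.
#'
#' @param label a [label_volume()].
#' @param plane a [sampling_plane()].
#' @param fov_mm in-plane field of view (square), mm.
#' @param pixel_mm in-plane sampling pitch, mm.
#' @return Area in mm2.
#' @export
true_dsa <- function(label, plane, fov_mm = 60, pixel_mm = 0.5) {
  stopifnot(inherits(label, "label_volume"), inherits(plane, "sampling_plane"))
  n <- round(fov_mm / pixel_mm)
  off <- (seq_len(n) - 1 - n %/% 2) * pixel_mm
  pu <- rep(off, times = n); pv <- rep(off, each = n)
  pts <- cbind(plane$origin[1] + pu * plane$e1[1] + pv * plane$e2[1],
               plane$origin[2] + pu * plane$e1[2] + pv * plane$e2[2],
               plane$origin[3] + pu * plane$e1[3] + pv * plane$e2[3])
  v <- cpp_sample_volume(as.numeric(label$classes), dim(label$classes),
                         label$spacing, label$origin, pts,
                         nearest = TRUE, fill = 0)
  sum(v == label_codes()[["dural_sac"]]) * pixel_mm^2
}
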