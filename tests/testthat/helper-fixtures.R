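# Shared fixtures, built once per test run.  Phantom generation is cheap
# (~1 s) but several files reuse the same volumes, so they are cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_phantom <- function() {
  cached("default_phantom", function() generate_phantom(phantom_config()))
}

straight_phantom <- function() {
  cached("straight_phantom", function()
    generate_phantom(phantom_config(curve_amplitude_mm = 0, noise_sd_hu = 0)))
}

# clean lumbar acquisition of the straight phantom
straight_volume <- function() {
  cached("straight_volume", function() {
    ph <- straight_phantom()
    apply_acquisition_mode(ph$volume, ph$label, "lumbar", noise_sd_hu = 0)
  })
}

# tilted-cylinder volume: a canal-like tube of radius r tilted by `theta`
# from the z axis in the x-z plane, with an analytically known section
make_cylinder <- function(r = 6, theta = 30 * pi / 180, n = 96, sp = 0.5) {
  ext <- (n - 1) * sp
  ax <- c(sin(theta), 0, cos(theta))
  ctr <- rep(ext / 2, 3)
  g <- expand.grid(x = (0:(n - 1)) * sp, y = (0:(n - 1)) * sp,
                   z = (0:(n - 1)) * sp)
  p <- cbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
  t <- p[, 1] * ax[1] + p[, 3] * ax[3]
  d2 <- (p[, 1] - t * ax[1])^2 + p[, 2]^2 + (p[, 3] - t * ax[3])^2
  lab <- array(as.integer(d2 <= r^2) * 2L, c(n, n, n))
  list(label = label_volume(lab, rep(sp, 3)),
       volume = ct_volume(array(as.numeric(lab == 2L) * 100, c(n, n, n)),
                          rep(sp, 3)),
       r = r, theta = theta, axis = ax, center = ctr)
}

# small slice set for fast training tests: reformatted slices of the default
# phantom, lumbar mode
tiny_slices <- function() {
  cached("tiny_slices", function() {
    ph <- default_phantom()
    duralseg:::phantom_slices(ph, "lumbar", fov_mm = 48, pixel_mm = 0.75,
                              seed = 4)
  })
}
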