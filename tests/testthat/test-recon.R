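test_that("log preprocessing maps intensities to line integrals", {
  I <- matrix(1, 8, 6)
  p <- preprocess_sinogram(I, I0 = 1)
  expect_true(all(p == 0))
  expect_equal(preprocess_sinogram(matrix(exp(-1), 2, 3), I0 = 1)[1, 1], 1)
  # clipping floor on nonpositive intensities
  I2 <- matrix(c(0, 0.5, 1), 3, 1)
  p2 <- preprocess_sinogram(I2, I0 = 1, floor_frac = 1e-3)
  expect_equal(attr(p2, "n_clipped"), 1L)
  expect_true(all(is.finite(p2)))
})

test_that("disk sinogram matches analytic chords in the contact regime", {
  # uniform disk, noiseless absorption imaging -> -log I equals mu x chord
  n <- 256; R <- 80; mu <- 0.005
  vol <- array(0, c(n, n, 1))
  xs <- (0:(n - 1)) - (n - 1) / 2
  vol[, , 1] <- (outer(xs^2, xs^2, `+`) <= R^2) * mu
  ds <- disk_sinogram(n, 1, R, mu)
  pr <- ilxpct:::cpp_project(vol, n, n, 1, 37 * pi / 180, n)
  expect_lt(max(abs(pr[, 1] - ds$sino[, 1])) / max(ds$sino), 0.02)
})

test_that("FBP reconstructs a uniform disk and is linear", {
  ds <- disk_sinogram(256, 400, 60, mu = 0.01)
  sl <- fbp_reconstruct(ds$sino, ds$angles)
  xs <- (0:255) - 127.5
  interior <- outer(xs^2, xs^2, `+`) < (0.8 * 60)^2
  expect_lt(abs(mean(sl[interior]) - 0.01) / 0.01, 0.05)
  expect_lt(sqrt(mean((sl[interior] - 0.01)^2)) / 0.01, 0.05)

  # linearity and the zero image
  expect_equal(fbp_reconstruct(3 * ds$sino, ds$angles), 3 * sl,
               tolerance = 1e-12)
  z <- fbp_reconstruct(matrix(0, 256, 400), ds$angles)
  expect_true(all(z == 0))
  expect_error(fbp_reconstruct(ds$sino[, 1, drop = FALSE], ds$angles[1]),
               "2 angles")
})

test_that("reconstruction error decreases with the number of views", {
  errs <- vapply(c(100, 400, 1200), function(na) {
    ds <- disk_sinogram(128, na, 30, mu = 0.01)
    sl <- fbp_reconstruct(ds$sino, ds$angles)
    xs <- (0:127) - 63.5
    interior <- outer(xs^2, xs^2, `+`) < (0.8 * 30)^2
    sqrt(mean((sl[interior] - 0.01)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("volume reconstruction matches slice reconstruction and symmetry", {
  # noiseless absorption acquisition of a z-aligned cylinder: every slice
  # reconstructs the same disk
  n <- 64
  spec <- phantom_spec(week_stage = 1, domain_mm = rep(0.576, 3),
                       voxel_um = 9, seed = 2,
                       suture = list(enabled = FALSE))
  ph <- rasterize_phantom(spec, list())
  ph$delta[] <- 0; ph$beta[] <- 0
  cyl <- cylinder_mask(n, 12)
  ph$beta[cyl] <- 1e-9
  g <- beam_geometry(n_angles = 200, distance_m = 0, photons = Inf)
  sino <- acquire_sinogram(ph, g, seed = 1)
  vol <- reconstruct_volume(sino)
  expect_identical(dim(vol$gray), rep(as.integer(n), 3L))
  s_mid <- vol$gray[, , 32]
  expect_lt(max(abs(vol$gray[, , 10] - s_mid)), 1e-10)

  # single-slice path equals the stack path
  p <- preprocess_sinogram(sino)
  s1 <- fbp_reconstruct(p[, , 5], sino$angles_deg)
  expect_equal(s1, vol$gray[, , 5], tolerance = 1e-12)
})

test_that("edge-enhanced reconstruction shows fringes above the noise", {
  spec <- small_spec(week = 1, seed = 8)
  ph <- build_phantom(spec)
  g <- beam_geometry(n_angles = 200, photons = 1e4)
  sino <- acquire_sinogram(ph, g, seed = 4)
  vol <- reconstruct_volume(sino)
  # background noise sigma outside the specimen
  bg <- vol$gray[ph$label == 0L & !dilate_mask(ph$masks$liver, 4)]
  sigma <- stats::sd(bg)
  # fringe amplitude near liver vessel walls
  shell <- dilate_mask(ph$label == 3L, 1) & ph$label != 3L
  fringe <- max(abs(vol$gray[shell]))
  expect_gt(fringe, 3 * sigma)
})

test_that("a single-column gain error reconstructs as a ring at its radius", {
  n <- 64
  spec <- phantom_spec(week_stage = 1, domain_mm = rep(0.576, 3),
                       voxel_um = 9, seed = 2,
                       suture = list(enabled = FALSE))
  ph <- rasterize_phantom(spec, list())
  g <- beam_geometry(n_angles = 180, photons = Inf)
  sino <- acquire_sinogram(ph, g, seed = 1)
  col <- 20L # offset from centre (n-1)/2 = 31.5 -> radius 12.5 px
  ring <- inject_ring_artifact(sino, col, 0.02)
  v0 <- reconstruct_volume(sino)
  v1 <- reconstruct_volume(ring)
  d <- abs(v1$gray[, , 32] - v0$gray[, , 32])
  xs <- (0:(n - 1)) - (n - 1) / 2
  rr <- sqrt(outer(xs^2, xs^2, `+`))
  # mean |difference| per 1-px radial bin peaks at the predicted radius
  bins <- floor(rr)
  prof <- tapply(d, bins, mean)
  peak_r <- as.numeric(names(prof))[which.max(prof)] + 0.5
  predicted <- abs(col - 1 - (n - 1) / 2)
  expect_lt(abs(peak_r - predicted), 1)
  expect_gt(max(prof), 0)
})
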