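test_that("wavelength and angle-step arithmetic match the beamline settings", {
  expect_equal(wavelength_angstrom(15), 0.8266, tolerance = 1e-4)
  expect_equal(beam_geometry(energy_kev = 15)$wavelength_angstrom,
               12.39842 / 15)
  g <- beam_geometry()
  a <- projection_angles(g)
  expect_equal(length(a), 1200L)
  expect_equal(diff(a)[1], 0.15)
  expect_error(beam_geometry(energy_kev = 5), "8, 72.5")
  expect_error(beam_geometry(arc_deg = 200), "arc_deg")
})

test_that("projection is linear in delta and exact on a uniform slab", {
  spec <- small_spec(seed = 1)
  ph <- rasterize_phantom(spec, list())
  g <- beam_geometry(energy_kev = 15, distance_m = 1)

  # empty volume -> zero maps
  ph0 <- ph
  ph0$delta[] <- 0; ph0$beta[] <- 0
  tr0 <- complex_transmission(ph0, 30, g)
  expect_true(all(tr0$phase_map == 0) && all(tr0$attenuation_map == 0))

  # doubling delta doubles the phase map exactly
  tr1 <- complex_transmission(ph, 45, g)
  ph2 <- ph
  ph2$delta <- 2 * ph$delta
  tr2 <- complex_transmission(ph2, 45, g)
  expect_equal(tr2$phase_map, 2 * tr1$phase_map, tolerance = 1e-12)

  # uniform slab of thickness t: phase = -(2 pi / lambda) delta t on rays
  # through the slab (axis-aligned projection, no interpolation error)
  phs <- ph
  phs$delta[] <- 0; phs$beta[] <- 0
  t_vox <- 20; dlt <- 1e-6
  phs$delta[, 21:40, ] <- dlt # slab spanning full x at angle 0
  tr <- complex_transmission(phs, 0, g)
  lambda_m <- g$wavelength_angstrom * 1e-10
  expected <- -(2 * pi / lambda_m) * dlt * t_vox * spec$voxel_um * 1e-6
  mid <- tr$phase_map[ceiling(nrow(tr$phase_map) / 2), 32]
  expect_equal(mid, expected, tolerance = 1e-6)

  expect_error(complex_transmission(ph, 180, g), "angle")
})

test_that("Fresnel propagator: contact identity, unitarity, composition", {
  g <- beam_geometry(energy_kev = 15, distance_m = 1)
  n <- 64
  ph_map <- matrix(0, n, n); ph_map[20:44, 25:39] <- 0.4
  at_map <- matrix(0, n, n); at_map[28:36, 28:36] <- 0.3

  # distance 0: exact contact image
  pr0 <- fresnel_propagate(ph_map, at_map, distance_m = 0, geometry = g)
  expect_equal(pr0$intensity, exp(-at_map), tolerance = 1e-12)

  # pure phase object: total intensity conserved (periodic propagator)
  u0 <- exp(1i * ph_map)
  u1 <- propagate_field(u0, 1, g$pixel_um, g$wavelength_angstrom,
                        pad = "none")
  expect_equal(sum(Mod(u1)^2), sum(Mod(u0)^2), tolerance = 1e-6)

  # composition: d1 then d2 equals d1 + d2
  ua <- propagate_field(
    propagate_field(u0, 0.35, g$pixel_um, g$wavelength_angstrom, "none"),
    0.65, g$pixel_um, g$wavelength_angstrom, "none"
  )
  ub <- propagate_field(u0, 1.0, g$pixel_um, g$wavelength_angstrom, "none")
  expect_lt(max(Mod(ua - ub)), 1e-8)

  expect_error(propagate_field(u0, -1, 9, 0.8266), ">= 0")

  # intensities are nonnegative and edge enhancement appears at the slab
  pr1 <- fresnel_propagate(ph_map, at_map, distance_m = 1, geometry = g)
  expect_true(all(pr1$intensity >= 0))
  expect_gt(max(pr1$intensity), 1.02) # bright fringe above flat field
})

test_that("acquisition is deterministic, noise-free at infinite photons", {
  spec <- small_spec(seed = 5)
  ph <- build_phantom(spec)
  g <- beam_geometry(n_angles = 24, photons = 1e4)
  s1 <- acquire_sinogram(ph, g, seed = 99)
  s2 <- acquire_sinogram(ph, g, seed = 99)
  expect_identical(s1$intensity, s2$intensity)
  expect_true(all(s1$intensity >= 0))
  expect_equal(dim(s1$intensity), c(64L, 24L, 64L))

  g_inf <- beam_geometry(n_angles = 4, photons = Inf)
  s_inf <- acquire_sinogram(ph, g_inf, seed = 1)
  tr <- complex_transmission(ph, 0, g_inf)
  pr <- fresnel_propagate(tr, geometry = g_inf)
  expect_equal(s_inf$intensity[, 1, ], pr$intensity, tolerance = 1e-12)

  g_bad <- beam_geometry(photons = 0)
  expect_error(acquire_sinogram(ph, g_bad, seed = 1), "photon")
})

test_that("ring injection perturbs exactly the named columns", {
  spec <- small_spec(seed = 6)
  ph <- build_phantom(spec)
  g <- beam_geometry(n_angles = 12, photons = Inf)
  s <- acquire_sinogram(ph, g, seed = 1)

  s0 <- inject_ring_artifact(s, 10, 0)
  expect_identical(s0$intensity, s$intensity)

  s1 <- inject_ring_artifact(s, 20, 0.02)
  d <- abs(s1$intensity - s$intensity)
  changed_cols <- which(apply(d, 1, max) > 0)
  expect_identical(changed_cols, 20L)
  expect_true(all(d[20, , ] > 0)) # at every angle (nonzero intensity there)
  expect_equal(s1$gain_profile[20], 1.02)

  expect_error(inject_ring_artifact(s, 200, 0.02), "detector width")
  expect_error(inject_ring_artifact(s, 10, 1.5), "gain_error")
})

test_that("edge contrast grows with distance and falls with energy", {
  # thin specimen slab with one vessel: the near-field behaviour of the
  # imaging-condition sweep at reduced scale
  spec <- phantom_spec(week_stage = 1, domain_mm = c(1.152, 1.152, 0.144),
                       voxel_um = 9, seed = 3)
  ph <- rasterize_phantom(spec, list())
  # one vessel cylinder along z in liver tissue
  cx <- 40; cy <- 64; r <- 3
  xs <- seq_len(128) - 1
  m2 <- outer((xs - cx)^2, (xs - cy)^2, `+`) <= r^2
  for (k in 1:16) ph$label[, , k][m2] <- 3L
  mats <- material_table(15)
  ph$delta <- array(mats$delta[match(ph$label, mats$label)], dim(ph$label))
  ph$beta <- array(mats$beta[match(ph$label, mats$label)], dim(ph$label))

  # profile across the vessel in the detector axis, mid-slab row
  segs <- tibble::tibble(x0 = cx + 1 - 12, y0 = 8, x1 = cx + 1 + 12,
                         y1 = 8)
  sweep <- contrast_sweep(
    ph, segs, energies_kev = c(12, 15, 20), distances_m = c(0.05, 1),
    geometry = beam_geometry(photons = Inf), angle_deg = 0
  )
  c_at <- function(e, d) {
    sweep$mean_contrast[sweep$energy_kev == e & sweep$distance_m == d]
  }
  expect_gt(c_at(15, 1), c_at(15, 0.05))
  expect_gte(c_at(12, 1), c_at(20, 1))
  expect_gte(c_at(12, 0.05), c_at(20, 0.05))

  # beyond the near-field optimum the fringe system broadens: the
  # bright/dark fringe pair across the vessel sits further apart at 5 m
  # than at 1 m
  fringe_width <- function(dist) {
    g <- beam_geometry(energy_kev = 15, distance_m = dist, photons = Inf)
    pr <- fresnel_propagate(complex_transmission(ph, 0, g), geometry = g)
    prof <- pr$intensity[(cx + 1 - 15):(cx + 1 + 15), 8]
    abs(which.max(prof) - which.min(prof))
  }
  expect_gt(fringe_width(5), fringe_width(1))
})
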