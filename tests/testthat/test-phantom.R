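test_that("vessel trees are deterministic forests obeying the radius rule", {
  spec <- small_spec(seed = 3)
  t1 <- build_vessel_tree(spec, "tumor", seed = 42)
  t2 <- build_vessel_tree(spec, "tumor", seed = 42)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)

  # forest: every child appears exactly once, no cycles
  expect_false(any(duplicated(t1$edges$child)))
  depth_ok <- TRUE
  parent_of <- integer(nrow(t1$nodes))
  parent_of[t1$edges$child] <- t1$edges$parent
  for (v in t1$edges$child) {
    seen <- integer(); cur <- v
    while (cur != 0 && !cur %in% seen) {
      seen <- c(seen, cur)
      cur <- if (cur <= length(parent_of)) parent_of[cur] else 0L
      if (cur == 0) break
      if (length(seen) > nrow(t1$nodes)) { depth_ok <- FALSE; break }
    }
  }
  expect_true(depth_ok)

  # child radius never exceeds parent radius; all radii positive
  expect_true(all(t1$nodes$radius_um > 0))
  expect_true(all(
    t1$nodes$radius_um[t1$edges$child] <=
      t1$nodes$radius_um[t1$edges$parent] + 1e-12
  ))

  # node positions inside the domain bounding box
  expect_true(all(t1$nodes$x_mm >= 0 & t1$nodes$x_mm <= spec$domain_mm[1]))
  expect_true(all(t1$nodes$y_mm >= 0 & t1$nodes$y_mm <= spec$domain_mm[2]))
  expect_true(all(t1$nodes$z_mm >= 0 & t1$nodes$z_mm <= spec$domain_mm[3]))

  # exact geometric radius rule: 90 x 0.8^3 at three generations
  tl <- build_vessel_tree(spec, "liver", seed = 7, root_radius_um = 90,
                          radius_ratio = 0.8, generations = 3)
  expect_equal(min(tl$nodes$radius_um), 90 * 0.8^3, tolerance = 1e-12)
  expect_equal(max(tl$nodes$gen), 3L)

  # zero tortuosity keeps segments straight (no wobble amplitude)
  t0 <- build_vessel_tree(spec, "tumor", seed = 9, tortuosity = 0)
  expect_true(all(t0$edges$amp_mm == 0))
})

test_that("rasterization voxelizes a cylinder to its analytic volume", {
  # tiny tumor so the test cylinder lies wholly in open liver tissue
  spec <- small_spec(seed = 1, tumor_volume_mm3 = 1e-4)
  r_vox <- 4
  vox_mm <- spec$voxel_um / 1000
  z0 <- 16; z1 <- 51 # voxel units; axis-aligned straight segment
  nodes <- tibble::tibble(
    id = 1:2,
    x_mm = c(0.218, 0.218), y_mm = c(0.358, 0.358),
    z_mm = c(z0, z1) * vox_mm,
    radius_um = c(r_vox, r_vox) * spec$voxel_um, gen = c(0L, 1L)
  )
  edges <- tibble::tibble(parent = 1L, child = 2L, amp_mm = 0, waves = 1L,
                          phase = 0, nrm_x = 1, nrm_y = 0, nrm_z = 0,
                          cluster = FALSE)
  tree <- structure(
    list(nodes = nodes, edges = edges, region = "liver", tortuosity = 0,
         seed = 1L),
    class = "vessel_tree"
  )
  ph <- rasterize_phantom(spec, list(tree), calibrate = FALSE)
  # count between the end planes (the stamped tube is a capsule; the
  # spherical caps sit outside this slab)
  interior_z <- (z0 + r_vox + 1):(z1 - r_vox)
  n_vessel <- sum(ph$label[, , interior_z] == 3L)
  analytic <- pi * r_vox^2 * length(interior_z)
  expect_lt(abs(n_vessel - analytic) / analytic, 0.05)
})

test_that("empty tree list gives zero vascular volume and density", {
  spec <- small_spec(seed = 2)
  ph <- rasterize_phantom(spec, list())
  gt <- tidy(ph)
  expect_equal(gt$vascular_volume_mm3, 0)
  expect_equal(gt$vascular_density_pct, 0)
})

test_that("ground-truth bookkeeping is exact and label grids deterministic", {
  spec <- small_spec(week = 2, seed = 11)
  ph1 <- build_phantom(spec)
  ph2 <- build_phantom(spec)
  expect_identical(ph1$label, ph2$label)

  gt <- tidy(ph1)
  vox_mm3 <- (spec$voxel_um * 1e-3)^3
  n_tumor <- sum(ph1$masks$tumor)
  n_vessel <- sum(ph1$label == 3L & ph1$masks$tumor)
  expect_identical(gt$tumor_volume_mm3, n_tumor * vox_mm3)
  expect_identical(gt$vascular_volume_mm3, n_vessel * vox_mm3)
  expect_identical(gt$vascular_density_pct, 100 * n_vessel / n_tumor)

  # mass conservation: every voxel carries exactly one label
  expect_identical(sum(tabulate(ph1$label + 1L, 5)), length(ph1$label))

  # vessel labels live inside tissue (liver or tumor support)
  expect_true(all(
    (ph1$masks$liver | ph1$masks$tumor)[ph1$label == 3L]
  ))

  # delta/beta nonnegative, shared shape
  expect_true(all(ph1$delta >= 0) && all(ph1$beta >= 0))
  expect_identical(dim(ph1$delta), dim(ph1$label))
})

test_that("week-2 phantom hits the target density within its reported bound", {
  spec <- small_spec(week = 2, seed = 21)
  ph <- build_phantom(spec)
  gt <- tidy(ph)
  expect_equal(spec$vascular_density_pct, 4.29)
  expect_lte(
    abs(gt$vascular_density_pct - 4.29) / 4.29,
    ph$density_bound + 1e-12
  )
  expect_lt(ph$density_bound, 0.10)
})

test_that("staged series orders volumes and densities as the xenografts do", {
  base <- small_spec(week = 1, seed = 31)
  series <- stage_series(base, seed = 31)
  gt <- dplyr::bind_rows(lapply(series, tidy))
  expect_identical(gt$week, 1:4)
  expect_true(all(diff(gt$tumor_volume_mm3) > 0))
  expect_identical(which.max(gt$vascular_density_pct), 2L)
  av <- vapply(series, function(p) p$spec$avascular_fraction, numeric(1))
  expect_true(all(diff(av[2:4]) > 0))
})

test_that("explicitly fixed density is honoured across the staged series", {
  base <- phantom_spec(week_stage = 1, domain_mm = rep(0.576, 3),
                       vascular_density_pct = 3, seed = 41)
  series <- stage_series(base, seed = 41)
  gt <- dplyr::bind_rows(lapply(series, tidy))
  bounds <- vapply(series, function(p) p$density_bound, numeric(1))
  expect_true(all(abs(gt$vascular_density_pct - 3) / 3 <= bounds + 1e-12))
  expect_lt(max(abs(gt$vascular_density_pct - 3) / 3), 0.10)
})

test_that("degenerate specs are rejected", {
  expect_error(phantom_spec(week_stage = 5), "week_stage")
  expect_error(phantom_spec(avascular_fraction = 1), "avascular")
  expect_error(phantom_spec(vascular_density_pct = 0), "density")
  expect_error(phantom_spec(domain_mm = rep(0.5, 3), voxel_um = 9),
               "divide")
  sp <- small_spec()
  sp$tumor_radius_mm <- 0
  expect_error(build_vessel_tree(sp, "tumor"), "empty region")
})
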