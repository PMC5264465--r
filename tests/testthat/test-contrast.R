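test_that("edge contrast follows the (Imax - Imin)/(Imax + Imin) rule", {
  # direct arithmetic: 200 vs 100 -> 1/3
  ec <- edge_contrast(c(100, 100, 100, 200, 200, 200))
  expect_equal(ec$contrast, 1 / 3)
  expect_equal(ec$i_max, 200)
  expect_equal(ec$i_min, 100)

  # ideal full-range step -> C = 1
  expect_equal(edge_contrast(c(0, 0, 0, 255, 255, 255))$contrast, 1)

  # equal extremes / flat profile -> 0, degenerate
  fl <- edge_contrast(rep(7, 10))
  expect_equal(fl$contrast, 0)
  expect_true(fl$degenerate)

  # falling edges give the same (order-free) contrast as rising ones
  expect_equal(edge_contrast(c(200, 200, 200, 100, 100, 100))$contrast,
               1 / 3)
  expect_error(edge_contrast(c(1, 2, 3)), "length")
})

test_that("segment extraction recovers the analytic two-level contrast", {
  # dark band on bright background
  img <- matrix(200, 64, 64)
  img[, 30:36] <- 50
  segs <- tibble::tibble(x0 = 32, y0 = 20, x1 = 32, y1 = 46)
  rc <- roi_edge_contrast(img, segs)
  expect_equal(rc$contrast, (200 - 50) / (200 + 50))

  # two identical segments -> identical contrast; summary attached
  segs2 <- dplyr::bind_rows(segs, segs)
  rc2 <- roi_edge_contrast(img, segs2)
  expect_equal(rc2$contrast[1], rc2$contrast[2])
  expect_equal(attr(rc2, "summary")$sd_contrast, 0)

  expect_error(
    roi_edge_contrast(img, tibble::tibble(x0 = 0, y0 = 1, x1 = 5, y1 = 1)),
    "outside"
  )
})

test_that("local contrast map equals the brute-force windowed CV", {
  set.seed(42)
  img <- matrix(runif(32 * 32, 50, 150), 32, 32)
  for (w in c(3, 7)) {
    got <- local_contrast_map(img, w = w)$c_map
    want <- brute_cv_map(img, w)
    expect_lt(max(abs(got - want)), 1e-10)
  }

  # constant image -> exactly zero
  expect_true(all(local_contrast_map(matrix(5, 20, 20))$c_map == 0))

  # scale invariance (exact)
  m1 <- local_contrast_map(img, 7)$c_map
  m3 <- local_contrast_map(3 * img, 7)$c_map
  expect_lt(max(abs(m1 - m3)), 1e-12)

  # window of {0, 2} in equal numbers: CV = sqrt(2 - 1)/1 = 1
  # checkerboard with one zero masked leaves a 3x3 window at (2,2) with
  # four 0s and four 2s
  ij <- outer(1:5, 1:5, `+`)
  chk <- 2 * (ij %% 2)
  msk <- matrix(FALSE, 5, 5); msk[1, 1] <- TRUE
  got <- local_contrast_map(chk, 3, mask = msk)$c_map
  expect_equal(got[2, 2], 1, tolerance = 1e-12)

  expect_error(local_contrast_map(img, w = 4), "odd")
})

test_that("masked pixels are excluded from the window averages", {
  img <- matrix(100, 32, 32)
  img[16, 16] <- 1e4 # spike to be masked out
  mask <- matrix(FALSE, 32, 32); mask[16, 16] <- TRUE
  cm <- local_contrast_map(img, 5, mask = mask)
  expect_true(all(cm$c_map == 0)) # constant once the spike is excluded
})

test_that("liver texture reads higher local contrast than tumor texture", {
  # identical textures -> equal means within sampling error
  set.seed(7)
  img <- matrix(100 + rnorm(64 * 64, 0, 10), 64, 64)
  tm <- matrix(FALSE, 64, 64); tm[5:28, 5:60] <- TRUE
  lm <- matrix(FALSE, 64, 64); lm[36:59, 5:60] <- TRUE
  tv <- tumor_vs_liver_contrast(img, tm, lm, w = 7)
  expect_lt(
    abs(tv$mean_contrast[1] - tv$mean_contrast[2]),
    0.3 * max(tv$mean_contrast)
  )

  # stronger texture under the liver mask -> liver mean exceeds tumor mean
  img2 <- img
  img2[lm] <- 100 + (img[lm] - 100) * 4
  tv2 <- tumor_vs_liver_contrast(img2, tm, lm, w = 7)
  expect_gt(tv2$mean_contrast[tv2$region == "liver"],
            tv2$mean_contrast[tv2$region == "tumor"])

  expect_error(tumor_vs_liver_contrast(img, tm, tm, w = 7), "disjoint")
  expect_error(
    tumor_vs_liver_contrast(img, matrix(FALSE, 64, 64), lm, w = 7),
    "empty"
  )
})

test_that("simulated projections show liver contrast above tumor contrast", {
  # suture disabled: its opaque shadow would otherwise dominate the tumor
  # window statistics (the projection workflow corrects it separately)
  spec <- small_spec(week = 1, seed = 12,
                     suture = list(enabled = FALSE))
  ph <- build_phantom(spec)
  g <- beam_geometry(photons = Inf)
  pr <- fresnel_propagate(complex_transmission(ph, 0, g), geometry = g)
  tm <- apply(ph$masks$tumor, c(1, 3), any)
  lm <- apply(ph$masks$liver & !ph$masks$tumor, c(1, 3), any) & !tm
  tv <- tumor_vs_liver_contrast(pr$intensity, tm, lm, w = 15)
  expect_gt(tv$mean_contrast[tv$region == "liver"],
            tv$mean_contrast[tv$region == "tumor"])
})
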