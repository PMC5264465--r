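# shared in-code fixtures for the suite

# small spec: 64^3 at 9 um (0.576 mm cube)
small_spec <- function(week = 2, seed = 1, ...) {
  phantom_spec(week_stage = week, domain_mm = rep(0.576, 3),
               voxel_um = 9, seed = seed, ...)
}

# analytic parallel-beam sinogram of a centred uniform disk
disk_sinogram <- function(n_det, n_angles, radius, mu = 0.01) {
  t <- (0:(n_det - 1)) - (n_det - 1) / 2
  chord <- ifelse(abs(t) < radius, 2 * sqrt(pmax(radius^2 - t^2, 0)), 0)
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  list(
    sino = matrix(rep(chord * mu, n_angles), n_det, n_angles),
    angles = angles, mu = mu, radius = radius
  )
}

# digital cylinder along z: voxel centres within `radius` voxels of the
# (cx, cy) axis
cylinder_mask <- function(n, radius, cx = (n - 1) / 2, cy = (n - 1) / 2,
                          nz = n) {
  xs <- 0:(n - 1)
  m2 <- outer((xs - cx)^2, (xs - cy)^2, `+`) <= radius^2
  arr <- array(FALSE, c(n, n, nz))
  for (k in seq_len(nz)) arr[, , k] <- m2
  arr
}

# brute-force windowed coefficient of variation (double loop, reflect pad)
brute_cv_map <- function(img, w) {
  r <- (w - 1) / 2
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  for (i in 1:n1) for (j in 1:n2) {
    vals <- c()
    for (a in (i - r):(i + r)) for (b in (j - r):(j + r)) {
      vals <- c(vals, img[refl(a, n1), refl(b, n2)])
    }
    m <- mean(vals)
    v <- mean(vals^2) - m^2
    out[i, j] <- if (m > 0) sqrt(max(v, 0)) / m else 0
  }
  out
}

# brute-force local thickness: distances to background computed directly,
# spheres painted from every foreground voxel (no ridge restriction)
brute_local_thickness <- function(mask) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, d)
  if (!nrow(fg)) return(out)
  r <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    dv <- sqrt(min(colSums((t(bg) - fg[i, ])^2)))
    r[i] <- dv
  }
  for (i in seq_len(nrow(fg))) {
    dia <- 2 * r[i] - 1
    for (j in seq_len(nrow(fg))) {
      if (sum((fg[j, ] - fg[i, ])^2) <= r[i]^2 + 1e-9 && out[fg[j, 1],
          fg[j, 2], fg[j, 3]] < dia) {
        out[fg[j, 1], fg[j, 2], fg[j, 3]] <- dia
      }
    }
  }
  out
}
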