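#' Convert intensities to line integrals
#'
#' Beer-Lambert preprocessing \eqn{p = -\log(I / I_0)} with \eqn{I_0}
#' the flat (air) intensity.  Nonpositive intensities are clipped at a
#' configurable floor (a fraction of \eqn{I_0}) before the log; the
#' number of clipped pixels is recorded as attribute `"n_clipped"`.
#'
#' @param sinogram A [acquire_sinogram()] result, or a bare numeric
#'   array/matrix of intensities.
#' @param I0 Flat-field intensity; defaults to the sinogram's
#'   `flat_value`, or 1 for bare arrays.
#' @param floor_frac Clipping floor as a fraction of `I0`.
#' @return Array of line integrals, same shape as the input intensity,
#'   with attributes `angles_deg` and `n_clipped`.
#' @export
preprocess_sinogram <- function(sinogram, I0 = NULL, floor_frac = 1e-6) {
  if (inherits(sinogram, "sinogram")) {
    I <- sinogram$intensity
    I0 <- I0 %||% sinogram$flat_value
    angles <- sinogram$angles_deg
  } else {
    I <- sinogram
    I0 <- I0 %||% 1
    angles <- attr(sinogram, "angles_deg")
  }
  stopifnot(I0 > 0, floor_frac > 0)
  n_clip <- sum(I < I0 * floor_frac)
  p <- -log(pmax(I, I0 * floor_frac) / I0)
  attr(p, "angles_deg") <- angles
  attr(p, "n_clipped") <- n_clip
  p
}

# frequency response of the band-limited ramp filter (Ram-Lak), length
# npad, optionally windowed
.ramp_filter <- function(npad, filter = c("ramlak", "shepp-logan", "hann")) {
  filter <- match.arg(filter)
  # spatial kernel of the band-limited ramp (tau = 1):
  # h(0) = 1/4, h(odd n) = -1/(pi n)^2, h(even n) = 0
  n <- c(0:(npad / 2 - 1), -(npad / 2):-1)
  h <- numeric(npad)
  h[n == 0] <- 0.25
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd])^2
  H <- Re(stats::fft(h))
  f <- abs(n) / npad # cycles per sample, 0..0.5
  w <- switch(filter,
    "ramlak" = rep(1, npad),
    "shepp-logan" = ifelse(f > 0, sin(pi * f) / (pi * f), 1),
    "hann" = 0.5 * (1 + cos(2 * pi * f))
  )
  H * w
}

#' Filtered back projection of one sinogram slice
#'
#' Standard parallel-beam FBP: each projection is convolved with the
#' band-limited ramp filter (Ram-Lak by default; Shepp-Logan and Hann
#' windows available), then back-projected with linear interpolation.
#' The rotation centre defaults to the detector midpoint.  The operator
#' is linear in its input.
#'
#' @param lsino Matrix of line integrals, detector columns x angles.
#' @param angles_deg Projection angles in degrees (uniform spacing over
#'   at most 180 degrees); defaults to the `angles_deg` attribute.
#' @param filter Filter name.
#' @param center_offset Rotation-centre offset from the detector
#'   midpoint, in pixels.
#' @param nx Output grid size (nx x nx); defaults to the detector width.
#' @return Reconstructed slice (nx x nx matrix), in units of attenuation
#'   per detector-pixel length.
#' @export
fbp_reconstruct <- function(lsino, angles_deg = NULL,
                            filter = c("ramlak", "shepp-logan", "hann"),
                            center_offset = 0, nx = NULL) {
  filter <- match.arg(filter)
  angles_deg <- angles_deg %||% attr(lsino, "angles_deg")
  stopifnot(is.matrix(lsino), !is.null(angles_deg))
  if (length(angles_deg) < 2) stop("need at least 2 angles", call. = FALSE)
  if (ncol(lsino) != length(angles_deg)) {
    stop("ncol(lsino) must equal length(angles_deg)", call. = FALSE)
  }
  vol <- .fbp_stack(
    array(lsino, c(nrow(lsino), ncol(lsino), 1)),
    angles_deg, filter, center_offset, nx
  )
  vol[, , 1]
}

# shared filtering + backprojection for a (n_det x n_angles x nz) stack
.fbp_stack <- function(p, angles_deg, filter, center_offset, nx) {
  n_det <- dim(p)[1]; n_a <- dim(p)[2]; nz <- dim(p)[3]
  nx <- as.integer(nx %||% n_det)
  npad <- 2^ceiling(log2(2 * n_det))
  H <- .ramp_filter(npad, filter)
  padded <- matrix(0, npad, n_a * nz)
  padded[seq_len(n_det), ] <- p
  Q <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / npad
  filt <- array(Q[seq_len(n_det), ], c(n_det, n_a, nz))
  dth <- (angles_deg[2] - angles_deg[1]) * pi / 180
  vol <- cpp_backproject(filt, n_det, n_a, nz,
                         angles_deg * pi / 180, nx, nx, center_offset)
  vol * dth
}

#' Reconstruct a full volume slice-by-slice
#'
#' Applies [preprocess_sinogram()] and slice-wise filtered back
#' projection to every detector row of the acquisition, stacking the
#' slices along the rotation axis.
#'
#' @param sinogram A [acquire_sinogram()] result.
#' @param filter Filter name, see [fbp_reconstruct()].
#' @param center_offset Rotation-centre offset in pixels.
#' @param I0,floor_frac Passed to [preprocess_sinogram()].
#' @param verbose Print per-volume timing.
#' @return An object of class `recon_volume`: `gray` (nx x nx x nz
#'   array), `voxel_um`, and provenance (geometry, filter, timing).
#' @export
reconstruct_volume <- function(sinogram, filter = c("ramlak", "shepp-logan",
                                                    "hann"),
                               center_offset = 0, I0 = NULL,
                               floor_frac = 1e-6, verbose = FALSE) {
  filter <- match.arg(filter)
  stopifnot(inherits(sinogram, "sinogram"))
  t0 <- proc.time()[["elapsed"]]
  p <- preprocess_sinogram(sinogram, I0 = I0, floor_frac = floor_frac)
  gray <- .fbp_stack(p, sinogram$angles_deg, filter, center_offset,
                     nx = dim(p)[1])
  elapsed <- proc.time()[["elapsed"]] - t0
  if (verbose) {
    message(sprintf("reconstructed %d slices in %.2f s (%.3f s/slice)",
                    dim(gray)[3], elapsed, elapsed / dim(gray)[3]))
  }
  structure(
    list(
      gray = gray, voxel_um = sinogram$voxel_um %||%
        sinogram$geometry$pixel_um,
      filter = filter, center_offset = center_offset,
      geometry = sinogram$geometry, gain_profile = sinogram$gain_profile,
      elapsed_s = elapsed
    ),
    class = "recon_volume"
  )
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf(
    "<recon_volume> %s voxels @ %g um, %s filter, gray in [%.4g, %.4g]\n",
    paste(dim(x$gray), collapse = "x"), x$voxel_um, x$filter,
    min(x$gray), max(x$gray)
  ))
  invisible(x)
}
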