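#' Projected phase and attenuation of a specimen
#'
#' Line-integral (projection) approximation of the complex transmission
#' of the voxel phantom along parallel rays at one rotation angle:
#' \deqn{\phi = -\frac{2\pi}{\lambda}\int \delta\, dl, \qquad
#'       A = \frac{4\pi}{\lambda}\int \beta\, dl,}
#' so the transmitted field is \eqn{\exp(i\phi - A/2)} and the contact
#' intensity \eqn{\exp(-A)}.  The stored delta/beta grids (tabulated at
#' the phantom's reference energy) are rescaled to the geometry's energy
#' as \eqn{\delta \propto E^{-2}}, \eqn{\beta \propto E^{-4}}.
#'
#' @param volume A [rasterize_phantom()] result (`phantom_volume`).
#' @param angle_deg Rotation angle in degrees, in [0, 180).
#' @param geometry A [beam_geometry()].
#' @param n_det Number of detector columns (default: the x-dimension of
#'   the volume).
#' @return List with matrices `phase_map` and `attenuation_map`
#'   (detector column x slice) and the angle.
#' @export
complex_transmission <- function(volume, angle_deg, geometry,
                                 n_det = NULL) {
  stopifnot(inherits(volume, "phantom_volume"),
            inherits(geometry, "beam_geometry"))
  if (length(volume$voxel_um) != 1) {
    stop("unsupported geometry: voxels must be isotropic", call. = FALSE)
  }
  if (angle_deg < 0 || angle_deg >= 180) {
    stop("angle_deg must lie in [0, 180)", call. = FALSE)
  }
  dims <- dim(volume$delta)
  n_det <- as.integer(n_det %||% dims[1])
  lambda_m <- wavelength_angstrom(geometry$energy_kev) * 1e-10
  dl_m <- volume$voxel_um * 1e-6
  fd <- (volume$ref_energy_kev / geometry$energy_kev)^2
  fb <- (volume$ref_energy_kev / geometry$energy_kev)^4
  th <- angle_deg * pi / 180
  pr <- cpp_project2(volume$delta, volume$beta,
                     dims[1], dims[2], dims[3], th, n_det)
  list(
    phase_map = -(2 * pi / lambda_m) * fd * dl_m * pr$A,
    attenuation_map = (4 * pi / lambda_m) * fb * dl_m * pr$B,
    angle_deg = angle_deg
  )
}

# frequency grid (cycles per metre) for an n-sample axis at pitch dx_m
.fft_freq <- function(n, dx_m) {
  c(seq_len(ceiling(n / 2)) - 1, -rev(seq_len(floor(n / 2)))) / (n * dx_m)
}

# memoised Fresnel chirp transfer function (rebuilt hundreds of times per
# acquisition otherwise)
.chirp_cache <- new.env(parent = emptyenv())
.fresnel_chirp <- function(N1, N2, dx, lz) {
  key <- sprintf("%d_%d_%.12g_%.12g", N1, N2, dx, lz)
  got <- .chirp_cache[[key]]
  if (!is.null(got)) return(got)
  f1 <- .fft_freq(N1, dx); f2 <- .fft_freq(N2, dx)
  chirp <- exp(-1i * pi * lz * outer(f1^2, f2^2, `+`))
  if (length(ls(.chirp_cache)) > 16) {
    rm(list = ls(.chirp_cache), envir = .chirp_cache)
  }
  .chirp_cache[[key]] <- chirp
  chirp
}

#' Propagate a complex field through free space
#'
#' Fresnel (paraxial) angular-spectrum propagation over `distance_m`,
#' implemented as multiplication by the chirp transfer function
#' \eqn{H(f) = \exp(-i\pi\lambda z |f|^2)} in Fourier space.  With
#' `pad = "none"` the operator is unitary on the periodic grid (total
#' intensity is conserved exactly and distances compose); `pad =
#' "replicate"` embeds the field in an edge-replicated frame before the
#' FFT to suppress wrap-around, then crops.
#'
#' @param field Complex matrix (the transmitted wavefield).
#' @param distance_m Propagation distance in metres (>= 0).
#' @param pixel_um Transverse sample pitch in micrometres.
#' @param wavelength_angstrom Wavelength in Angstrom.
#' @param pad `"replicate"` or `"none"`.
#' @return Complex matrix of the propagated field, same size as input.
#' @export
propagate_field <- function(field, distance_m, pixel_um,
                            wavelength_angstrom,
                            pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  if (distance_m < 0) stop("distance_m must be >= 0", call. = FALSE)
  if (distance_m == 0) return(field)
  lambda_m <- wavelength_angstrom * 1e-10
  dx <- pixel_um * 1e-6
  n1 <- nrow(field); n2 <- ncol(field)
  if (pad == "replicate") {
    N1 <- 2^ceiling(log2(max(n1 * 1.5, 8)))
    N2 <- 2^ceiling(log2(max(n2 * 1.5, 8)))
    p1 <- floor((N1 - n1) / 2); p2 <- floor((N2 - n2) / 2)
    big <- matrix(0 + 0i, N1, N2)
    ri <- pmin(pmax(seq_len(N1) - p1, 1), n1)
    ci <- pmin(pmax(seq_len(N2) - p2, 1), n2)
    big[] <- field[ri, ci]
    u <- big
  } else {
    N1 <- n1; N2 <- n2; p1 <- p2 <- 0
    u <- field
  }
  # sampling adequacy of the chirp: z <= N dx^2 / lambda per axis
  zc <- min(N1, N2) * dx^2 / lambda_m
  if (distance_m > zc) {
    warning(sprintf(
      "propagation distance %.3g m exceeds the aliasing-safe limit %.3g m",
      distance_m, zc
    ))
  }
  chirp <- .fresnel_chirp(N1, N2, dx, lambda_m * distance_m)
  U <- stats::fft(u) * chirp
  u2 <- stats::fft(U, inverse = TRUE) / length(U)
  u2[p1 + seq_len(n1), p2 + seq_len(n2)]
}

#' Edge-enhanced projection by Fresnel propagation
#'
#' Builds the transmitted wavefield \eqn{\exp(i\,\mathrm{phase} -
#' \mathrm{attenuation}/2)} and propagates it to the detector plane; the
#' recorded intensity is the squared modulus.  At distance 0 this is the
#' pure absorption (contact) image \eqn{\exp(-\mathrm{attenuation})},
#' exactly.
#'
#' @param phase_map,attenuation_map Matrices from
#'   [complex_transmission()] (or a list with those elements as the first
#'   argument).
#' @param distance_m Object-to-detector distance; default from geometry.
#' @param geometry A [beam_geometry()].
#' @param pad Padding policy, see [propagate_field()].
#' @return An object of class `projection_image`: list with the
#'   nonnegative `intensity` matrix, the angle and the geometry.
#' @export
fresnel_propagate <- function(phase_map, attenuation_map = NULL,
                              distance_m = NULL, geometry = NULL,
                              pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  angle_deg <- NA_real_
  if (is.list(phase_map) && !is.null(phase_map$phase_map)) {
    attenuation_map <- phase_map$attenuation_map
    angle_deg <- phase_map$angle_deg %||% NA_real_
    phase_map <- phase_map$phase_map
  }
  stopifnot(inherits(geometry, "beam_geometry"),
            is.matrix(phase_map), is.matrix(attenuation_map),
            all(dim(phase_map) == dim(attenuation_map)))
  distance_m <- distance_m %||% geometry$distance_m
  if (distance_m < 0) stop("distance_m must be >= 0", call. = FALSE)
  if (distance_m == 0) {
    intensity <- exp(-attenuation_map)
  } else {
    u0 <- exp(1i * phase_map - attenuation_map / 2)
    u <- propagate_field(u0, distance_m, geometry$pixel_um,
                         geometry$wavelength_angstrom, pad = pad)
    intensity <- Mod(u)^2
  }
  structure(
    list(intensity = intensity, angle_deg = angle_deg,
         distance_m = distance_m, geometry = geometry),
    class = "projection_image"
  )
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf(
    "<projection_image> %d x %d, angle %s deg, z = %g m, I in [%.4g, %.4g]\n",
    nrow(x$intensity), ncol(x$intensity), format(x$angle_deg),
    x$distance_m, min(x$intensity), max(x$intensity)
  ))
  invisible(x)
}

#' Simulate a full tomographic acquisition
#'
#' One edge-enhanced projection per rotation angle, each corrupted by
#' per-pixel Poisson noise at the geometry's photon proxy (counts are
#' drawn with mean `photons x intensity` and renormalised; `photons =
#' Inf` disables noise).  Deterministic for a fixed seed.
#'
#' @param volume A `phantom_volume`.
#' @param geometry A [beam_geometry()].
#' @param seed Integer RNG seed.
#' @param pad Padding policy for the propagator.
#' @param n_det Number of detector columns (default: volume x-dimension).
#' @return An object of class `sinogram`: intensity array
#'   (detector x angle x slice), angles (degrees), per-column
#'   `gain_profile` (all 1), `flat_value` (air intensity) and geometry.
#' @export
acquire_sinogram <- function(volume, geometry, seed = 1,
                             pad = c("replicate", "none"), n_det = NULL) {
  pad <- match.arg(pad)
  stopifnot(inherits(volume, "phantom_volume"),
            inherits(geometry, "beam_geometry"))
  if (!is.infinite(geometry$photons) && geometry$photons <= 0) {
    stop("photon level must be > 0", call. = FALSE)
  }
  angles <- projection_angles(geometry)
  dims <- dim(volume$delta)
  n_det <- as.integer(n_det %||% dims[1])
  nz <- dims[3]
  sino <- array(0, c(n_det, geometry$n_angles, nz))
  withr::with_seed(seed, {
    for (a in seq_along(angles)) {
      tr <- complex_transmission(volume, angles[a], geometry, n_det = n_det)
      pr <- fresnel_propagate(tr, geometry = geometry, pad = pad)
      I <- pr$intensity
      if (is.finite(geometry$photons)) {
        I <- matrix(
          stats::rpois(length(I), geometry$photons * I) / geometry$photons,
          nrow(I), ncol(I)
        )
      }
      sino[, a, ] <- I
    }
  })
  structure(
    list(
      intensity = sino, angles_deg = angles,
      gain_profile = rep(1, n_det), flat_value = 1,
      geometry = geometry, voxel_um = volume$voxel_um, seed = seed
    ),
    class = "sinogram"
  )
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<sinogram> %d detector cols x %d angles x %d slices, step %.4g deg\n",
    d[1], d[2], d[3], diff(x$angles_deg[1:2])
  ))
  invisible(x)
}

#' Inject a detector-gain (ring) artifact
#'
#' Multiplies the named detector columns by `1 + gain_error` at every
#' angle, emulating miscalibrated detector elements; after filtered back
#' projection each perturbed column produces a concentric ring at radius
#' `|column - centre| x pixel size`.
#'
#' @param sinogram A [acquire_sinogram()] result.
#' @param columns Integer detector column indices (1-based).
#' @param gain_errors Fractional gain errors, one per column or recycled;
#'   must satisfy `|gain| < 1`.
#' @return The sinogram with perturbed columns and an updated
#'   `gain_profile`.
#' @export
inject_ring_artifact <- function(sinogram, columns, gain_errors) {
  stopifnot(inherits(sinogram, "sinogram"))
  n_det <- dim(sinogram$intensity)[1]
  columns <- as.integer(columns)
  if (any(columns < 1 | columns > n_det)) {
    stop("columns must lie within the detector width", call. = FALSE)
  }
  gain_errors <- rep_len(gain_errors, length(columns))
  if (any(abs(gain_errors) >= 1)) {
    stop("|gain_error| must be < 1", call. = FALSE)
  }
  for (i in seq_along(columns)) {
    sinogram$intensity[columns[i], , ] <-
      sinogram$intensity[columns[i], , ] * (1 + gain_errors[i])
    sinogram$gain_profile[columns[i]] <-
      sinogram$gain_profile[columns[i]] * (1 + gain_errors[i])
  }
  sinogram
}
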