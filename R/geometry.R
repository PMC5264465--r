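#' X-ray wavelength from photon energy
#'
#' Converts photon energy in keV to wavelength in Angstrom using
#' \eqn{\lambda = hc/E} with \eqn{hc = 12.39842} keV A.
#'
#' @param energy_kev Photon energy in keV.
#' @return Wavelength in Angstrom.
#' @examples
#' wavelength_angstrom(15) # 0.8266 A
#' @export
wavelength_angstrom <- function(energy_kev) {
  stopifnot(is.numeric(energy_kev), all(energy_kev > 0))
  12.39842 / energy_kev
}

#' Beam and detector geometry
#'
#' Bundles the acquisition parameters of a parallel-beam synchrotron
#' imaging setup: photon energy, object-to-detector propagation distance,
#' source distance, detector pixel size, and the rotation protocol.
#' The source sits tens of metres upstream while the detector is at most a
#' few metres downstream, so the beam is modelled as a plane wave
#' (magnification 1); geometric blur is not modelled.
#'
#' @param energy_kev Photon energy in keV; must lie in the beamline's
#'   8--72.5 keV range.
#' @param distance_m Object-to-detector distance in metres (>= 0; 0 is the
#'   contact / pure-absorption regime).
#' @param source_m Source-to-object distance in metres.
#' @param pixel_um Effective detector pixel size in micrometres.
#' @param n_angles Number of projections over the arc.
#' @param arc_deg Angular range in degrees, in (0, 180].
#' @param photons Expected photon count per detector pixel through air
#'   (exposure proxy driving Poisson noise); `Inf` disables noise.
#' @return An object of class `beam_geometry`.
#' @examples
#' g <- beam_geometry(energy_kev = 15, distance_m = 1)
#' g$wavelength_angstrom
#' @export
beam_geometry <- function(energy_kev = 15, distance_m = 1, source_m = 34,
                          pixel_um = 9, n_angles = 1200, arc_deg = 180,
                          photons = 1e4) {
  stopifnot(length(energy_kev) == 1, length(distance_m) == 1)
  if (energy_kev < 8 || energy_kev > 72.5) {
    stop("energy_kev must lie within the beamline range [8, 72.5] keV",
         call. = FALSE)
  }
  if (distance_m < 0 || source_m < 0) {
    stop("distances must be >= 0", call. = FALSE)
  }
  if (pixel_um <= 0) stop("pixel_um must be > 0", call. = FALSE)
  if (n_angles < 1) stop("n_angles must be >= 1", call. = FALSE)
  if (arc_deg <= 0 || arc_deg > 180) {
    stop("arc_deg must lie in (0, 180]", call. = FALSE)
  }
  structure(
    list(
      energy_kev = energy_kev,
      wavelength_angstrom = wavelength_angstrom(energy_kev),
      distance_m = distance_m,
      source_m = source_m,
      pixel_um = pixel_um,
      n_angles = as.integer(n_angles),
      arc_deg = arc_deg,
      photons = photons
    ),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("<beam_geometry> %.4g keV (lambda %.4f A), z = %.3g m, ",
           "pixel %.3g um\n  %d projections over %g deg ",
           "(step %.4g deg), photon proxy %s\n"),
    x$energy_kev, x$wavelength_angstrom, x$distance_m, x$pixel_um,
    x$n_angles, x$arc_deg, x$arc_deg / x$n_angles,
    format(x$photons)
  ))
  invisible(x)
}

#' Projection angles of a geometry
#'
#' @param geometry A [beam_geometry()].
#' @return Numeric vector of angles in degrees, uniformly spaced over
#'   `[0, arc_deg)`.
#' @export
projection_angles <- function(geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  seq(0, geometry$arc_deg, length.out = geometry$n_angles + 1)[
    seq_len(geometry$n_angles)
  ]
}
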