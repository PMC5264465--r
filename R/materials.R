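#' Optical constants of the phantom materials
#'
#' Built-in table of the complex refractive index decrement delta and
#' absorption index beta (n = 1 - delta + i beta) for the materials a
#' fixed, ethanol-dehydrated liver specimen is composed of: water-like
#' soft liver tissue, slightly denser tumor tissue, ethanol-filled vessel
#' lumina, a dense polymer suture, and background air.  Reference values
#' are given at 15 keV; delta scales as \eqn{E^{-2}} and beta as
#' \eqn{E^{-4}} (photoelectric-dominated regime) across energies.
#'
#' @param energy_kev Photon energy in keV at which to evaluate the table.
#' @param overrides Optional named list `list(material = c(delta, beta))`
#'   replacing the built-in reference values (at 15 keV) before scaling.
#' @return A tibble with columns `material`, `label`, `delta`, `beta`.
#' @examples
#' material_table(15)
#' @export
material_table <- function(energy_kev = 15, overrides = NULL) {
  ref <- list(
    background = c(0, 0),
    liver      = c(1.00e-06, 1.10e-09),
    tumor      = c(1.06e-06, 1.25e-09),
    vessel     = c(8.10e-07, 7.00e-10),
    suture     = c(2.00e-06, 1.50e-07)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (nm in names(overrides)) {
      stopifnot(nm %in% names(ref), length(overrides[[nm]]) == 2)
      ref[[nm]] <- as.numeric(overrides[[nm]])
    }
  }
  fd <- (15 / energy_kev)^2
  fb <- (15 / energy_kev)^4
  tibble::tibble(
    material = names(ref),
    label = .label_codes()[names(ref)],
    delta = vapply(ref, `[`, numeric(1), 1) * fd,
    beta = vapply(ref, `[`, numeric(1), 2) * fb
  )
}

# integer codes used in the phantom label grid
.label_codes <- function() {
  c(background = 0L, liver = 1L, tumor = 2L, vessel = 3L, suture = 4L)
}
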