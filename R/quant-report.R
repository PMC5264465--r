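#' Assemble a per-specimen quantification report row
#'
#' One row of the week-series table: tumor volume, intratumoral vascular
#' volume, vascular density (vascular volume / tumor volume, percent),
#' smallest vessel diameter and a diameter histogram.  The minimum
#' diameter is floored at twice the voxel size (the resolution limit of
#' the voxel grid); `sub_resolution` flags when the floor binds.
#'
#' @param tumor_volume_mm3,vascular_volume_mm3 Volumes in mm^3.
#' @param min_diameter_um Smallest vessel diameter in micrometres (before
#'   flooring).
#' @param voxel_um Voxel size in micrometres (sets the resolution floor).
#' @param week Week stage (integer) or NA.
#' @param diameter_histogram Tibble with columns `bin_lo_um`, `bin_hi_um`,
#'   `count`, or NULL.
#' @return A one-row tibble of class `quant_report` with the histogram
#'   attached as attribute `"diameter_histogram"`.
#' @export
quant_report <- function(tumor_volume_mm3, vascular_volume_mm3,
                         min_diameter_um = NA_real_, voxel_um = 9,
                         week = NA_integer_, diameter_histogram = NULL) {
  stopifnot(tumor_volume_mm3 >= 0, vascular_volume_mm3 >= 0)
  dens <- if (tumor_volume_mm3 > 0) {
    100 * vascular_volume_mm3 / tumor_volume_mm3
  } else NA_real_
  floor_um <- 2 * voxel_um
  sub_res <- is.finite(min_diameter_um) && min_diameter_um < floor_um
  out <- tibble::tibble(
    week = as.integer(week),
    tumor_volume_mm3 = tumor_volume_mm3,
    vascular_volume_mm3 = vascular_volume_mm3,
    vascular_density_pct = dens,
    min_diameter_um = if (is.finite(min_diameter_um)) {
      max(min_diameter_um, floor_um)
    } else NA_real_,
    sub_resolution = sub_res
  )
  attr(out, "diameter_histogram") <- diameter_histogram
  class(out) <- c("quant_report", class(out))
  out
}

# histogram of diameters (um) at 1-voxel bin width
diameter_histogram <- function(diameters_um, voxel_um = 9) {
  if (!length(diameters_um)) {
    return(tibble::tibble(bin_lo_um = numeric(), bin_hi_um = numeric(),
                          count = integer()))
  }
  top <- ceiling(max(diameters_um) / voxel_um) * voxel_um
  edges <- seq(0, top, by = voxel_um)
  idx <- pmin(pmax(ceiling(diameters_um / voxel_um), 1L), length(edges) - 1)
  tibble::tibble(
    bin_lo_um = edges[-length(edges)],
    bin_hi_um = edges[-1],
    count = tabulate(idx, nbins = length(edges) - 1)
  )
}
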