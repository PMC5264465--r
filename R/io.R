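#' Write a 3D volume as a multi-page TIFF stack
#'
#' Gray values are affinely mapped to [0, 1] for 32-bit float TIFF
#' storage; the mapping (`offset`, `scale`) is recorded in a JSON
#' sidecar (`<path>.json`) together with the voxel size so
#' [read_volume_tiff()] restores the original values.
#'
#' @param x `recon_volume`, `phantom_volume` (its label grid is written
#'   alongside) or a 3D numeric array.
#' @param path Output TIFF path.
#' @param voxel_um Voxel size for bare arrays.
#' @return Invisibly, the path.
#' @export
write_volume_tiff <- function(x, path, voxel_um = NULL) {
  if (inherits(x, "recon_volume")) {
    arr <- x$gray; voxel_um <- x$voxel_um
  } else if (inherits(x, "phantom_volume")) {
    arr <- x$delta; voxel_um <- x$voxel_um
  } else {
    arr <- x
    if (is.null(voxel_um)) stop("voxel_um required for bare arrays",
                                call. = FALSE)
  }
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  slices <- lapply(seq_len(dim(arr)[3]),
                   function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset = lo, scale = scale, voxel_um = voxel_um,
         dim = dim(arr)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a TIFF volume written by [write_volume_tiff()]
#'
#' Externally produced grayscale TIFF stacks are read as-is (no sidecar
#' required; values stay on the stored scale).
#'
#' @param path TIFF path.
#' @return 3D numeric array with attribute `voxel_um` when the sidecar
#'   is present.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    arr <- arr * meta$scale + meta$offset
    attr(arr, "voxel_um") <- meta$voxel_um
  }
  arr
}

#' Write a sinogram as a TIFF stack with a geometry sidecar
#'
#' The intensity array (detector x angle x slice) is written with
#' [write_volume_tiff()]; the acquisition geometry, angles and gain
#' profile go to an additional `<path>.geometry.json` sidecar.
#'
#' @param sinogram A [acquire_sinogram()] result.
#' @param path Output TIFF path.
#' @return Invisibly, the path.
#' @export
write_sinogram <- function(sinogram, path) {
  stopifnot(inherits(sinogram, "sinogram"))
  write_volume_tiff(sinogram$intensity, path,
                    voxel_um = sinogram$voxel_um)
  g <- sinogram$geometry
  jsonlite::write_json(
    list(
      energy_kev = g$energy_kev, distance_m = g$distance_m,
      source_m = g$source_m, pixel_um = g$pixel_um,
      n_angles = g$n_angles, arc_deg = g$arc_deg, photons = g$photons,
      angles_deg = sinogram$angles_deg,
      gain_profile = sinogram$gain_profile,
      flat_value = sinogram$flat_value, seed = sinogram$seed
    ),
    paste0(path, ".geometry.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Wrap an externally supplied gray volume for quantification
#'
#' @param gray 3D numeric array (e.g. from [read_volume_tiff()]).
#' @param voxel_um Voxel size in micrometres.
#' @return A `recon_volume` usable with [segment_vessels()] and
#'   [quantify_specimen()].
#' @export
as_recon_volume <- function(gray, voxel_um = 9) {
  stopifnot(is.array(gray), length(dim(gray)) == 3)
  structure(
    list(gray = gray, voxel_um = voxel_um, filter = "external",
         center_offset = 0, geometry = NULL, gain_profile = NULL,
         elapsed_s = NA_real_),
    class = "recon_volume"
  )
}

#' Write a phantom's grids and ground truth to disk
#'
#' Delta, beta and label grids as TIFF stacks plus a JSON ground-truth
#' sidecar.
#'
#' @param phantom A `phantom_volume`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(
    delta = file.path(dir, "delta.tif"),
    beta = file.path(dir, "beta.tif"),
    label = file.path(dir, "label.tif"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_volume_tiff(phantom$delta, p[["delta"]], phantom$voxel_um)
  write_volume_tiff(phantom$beta, p[["beta"]], phantom$voxel_um)
  write_volume_tiff(phantom$label + 0, p[["label"]], phantom$voxel_um)
  gt <- as.list(tidy.phantom_volume(phantom))
  gt$density_bound <- phantom$density_bound
  jsonlite::write_json(gt, p[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(p)
}
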