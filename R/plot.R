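#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a local contrast map
#'
#' @param object A [local_contrast_map()].
#' @param ... Unused.
#' @return A ggplot raster of the per-pixel local contrast.
#' @method autoplot local_contrast_map
#' @export
autoplot.local_contrast_map <- function(object, ...) {
  df <- tidyr::expand_grid(
    x = seq_len(nrow(object$c_map)), y = seq_len(ncol(object$c_map))
  )
  df$contrast <- as.vector(object$c_map)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$contrast)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Local contrast map (W = %d)", object$window),
      x = NULL, y = NULL, fill = "C"
    )
}

#' Plot a week-series summary
#'
#' Mean +- SD of each metric over the four growth stages.
#'
#' @param object A [week_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot week_series
#' @export
autoplot.week_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$week, .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "week", y = NULL)
}

#' Display one slice of a volume
#'
#' @param volume `recon_volume`, `phantom_volume` or 3D array.
#' @param z Slice index (default: middle slice).
#' @param what For phantoms: `"delta"`, `"beta"` or `"label"`.
#' @return A ggplot raster.
#' @export
plot_slice <- function(volume, z = NULL, what = "delta") {
  arr <- if (inherits(volume, "recon_volume")) {
    volume$gray
  } else if (inherits(volume, "phantom_volume")) {
    volume[[what]] + 0
  } else volume
  z <- z %||% ceiling(dim(arr)[3] / 2)
  m <- arr[, , z]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$gray <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice z = %d", z), x = NULL, y = NULL)
}

#' Display a sinogram slice
#'
#' @param sinogram A [acquire_sinogram()] result.
#' @param slice Axial slice index (default: middle).
#' @return A ggplot raster (detector column vs angle).
#' @export
plot_sinogram <- function(sinogram, slice = NULL) {
  stopifnot(inherits(sinogram, "sinogram"))
  slice <- slice %||% ceiling(dim(sinogram$intensity)[3] / 2)
  m <- sinogram$intensity[, , slice]
  df <- tidyr::expand_grid(detector = seq_len(nrow(m)),
                           angle = seq_len(ncol(m)))
  df$intensity <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$angle, .data$detector,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(title = sprintf("sinogram, slice %d", slice))
}
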