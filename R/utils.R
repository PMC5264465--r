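# internal helpers shared across modules

# reflect-pad a matrix by r rows/cols on every side (edge not duplicated
# at r = 0; mirror includes the edge pixel's neighbours first)
pad_reflect <- function(m, r) {
  if (r == 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(pmin(r:1, n1), 1:n1, pmax(n1 - (1:r), 1))
  ci <- c(pmin(r:1, n2), 1:n2, pmax(n2 - (1:r), 1))
  m[ri, ci, drop = FALSE]
}

# sliding w x w window sums with reflective boundary, via integral image
box_sum <- function(m, w) {
  stopifnot(w %% 2 == 1, w >= 1)
  r <- (w - 1) / 2
  p <- pad_reflect(m, r)
  cs <- apply(apply(p, 2, cumsum), 1, cumsum) # transposed integral image
  cs <- t(cs)
  np1 <- nrow(p); np2 <- ncol(p)
  z <- matrix(0, np1 + 1, np2 + 1)
  z[-1, -1] <- cs
  i0 <- 1:nrow(m); j0 <- 1:ncol(m)
  z[i0 + 2 * r + 1, j0 + 2 * r + 1, drop = FALSE] -
    z[i0, j0 + 2 * r + 1, drop = FALSE] -
    z[i0 + 2 * r + 1, j0, drop = FALSE] +
    z[i0, j0, drop = FALSE]
}

# bilinear sample of matrix `img` at fractional (row, col) positions
bilinear_sample <- function(img, rr, cc) {
  n1 <- nrow(img); n2 <- ncol(img)
  rr <- pmin(pmax(rr, 1), n1)
  cc <- pmin(pmax(cc, 1), n2)
  r0 <- pmin(floor(rr), n1 - 1L); c0 <- pmin(floor(cc), n2 - 1L)
  fr <- rr - r0; fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximising the between-class variance,
#' computed on a fixed number of equal-width bins over the data range.
#'
#' @param x Numeric vector (or array) of gray values.
#' @param n_bins Number of histogram bins.
#' @return The threshold gray value (bin edge).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values for thresholding", call. = FALSE)
  rg <- range(x)
  if (rg[1] == rg[2]) return(rg[1])
  br <- seq(rg[1], rg[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  br[k + 1]
}

# coerce recon_volume / phantom_volume / raw array inputs to a gray array
as_gray_array <- function(volume) {
  if (inherits(volume, "recon_volume")) return(volume$gray)
  if (is.array(volume) && length(dim(volume)) == 3) return(volume)
  stop("expected a recon_volume or a 3D array", call. = FALSE)
}

voxel_um_of <- function(volume, voxel_um = NULL) {
  if (!is.null(voxel_um)) return(voxel_um)
  if (inherits(volume, "recon_volume")) return(volume$voxel_um)
  stop("voxel_um must be supplied for a bare array", call. = FALSE)
}
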