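#' Integer lattice offsets of a Euclidean disc
#'
#' Offsets `(dy, dx)` with `dy^2 + dx^2 <= radius^2`; radius 3 gives the
#' 29-pixel disc inscribed in a 7 x 7 window.
#'
#' @param radius disc radius in pixels (>= 0).
#' @return two-column integer matrix of offsets.
#' @export
disc_offsets <- function(radius) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  as.matrix(g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE])
}

#' Circular spatial binning of a TCSPC cube
#'
#' Replaces each pixel's decay by the sum of decays over its neighbours
#' within a Euclidean disc (radius 3 = the classic "7 x 7 circular
#' binning"). Implemented as an exact integer shift-and-add; pixels near the
#' border sum only the offsets that fall inside the image.
#'
#' @param cube a [tcspc_cube()].
#' @param radius disc radius in pixels; 0 returns the cube unchanged.
#' @return a binned [tcspc_cube()].
#' @export
circular_bin <- function(cube, radius = 3) {
  stopifnot(inherits(cube, "tcspc_cube"))
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(cube)
  d <- dim(cube$counts)
  m <- matrix(cube$counts, d[1] * d[2], d[3])
  acc <- matrix(0, d[1] * d[2], d[3])
  off <- disc_offsets(radius)
  for (k in seq_len(nrow(off))) {
    dy <- off[k, 1]; dx <- off[k, 2]
    ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
    xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
    src <- as.vector(outer(ys, (xs - 1L) * d[1], "+"))
    tgt <- as.vector(outer(ys - dy, (xs - dx - 1L) * d[1], "+"))
    acc[tgt, ] <- acc[tgt, ] + m[src, ]
  }
  out <- array(acc, d)
  tcspc_cube(out, period = cube$period, bin_edges = cube$bin_edges,
             pixel_size_um = cube$pixel_size_um,
             frequency_mhz = cube$frequency_mhz)
}

#' Intensity threshold mask
#'
#' Includes pixels whose (binned) intensity lies between `low_fraction` and
#' `high_fraction` of the image maximum — e.g. the standard "15% to 100%"
#' window.
#'
#' @param intensity 2-D photon-count grid.
#' @param low_fraction,high_fraction fractions of the image maximum,
#'   `0 <= low <= high <= 1`.
#' @return logical matrix.
#' @export
intensity_threshold_mask <- function(intensity, low_fraction = 0.15,
                                     high_fraction = 1) {
  stopifnot(is.matrix(intensity),
            low_fraction >= 0, high_fraction <= 1,
            low_fraction <= high_fraction)
  mx <- max(intensity)
  if (mx <= 0) {
    warning("all-zero intensity image; mask is all FALSE")
    return(matrix(FALSE, nrow(intensity), ncol(intensity)))
  }
  intensity >= low_fraction * mx & intensity <= high_fraction * mx
}

#' Pixel-wise mono-exponential lifetime map
#'
#' Fits each masked pixel's (binned) decay with [fit_mono()] and returns the
#' per-pixel apparent lifetime; pixels outside the mask, under the photon
#' floor, or failing to converge are `NA`.
#'
#' @param cube a (typically circularly binned) [tcspc_cube()].
#' @param irf `irf_model`.
#' @param mask logical matrix of pixels to fit.
#' @param options [fit_options()].
#' @param min_photons per-pixel photon floor after binning (default 100).
#' @return matrix of lifetimes (ns) with `NA` where undefined, class
#'   `lifetime_map`.
#' @export
fit_pixelwise <- function(cube, irf, mask,
                          options = fit_options(),
                          min_photons = 100) {
  stopifnot(inherits(cube, "tcspc_cube"), is.logical(mask))
  d <- dim(cube$counts)
  if (!all(dim(mask) == d[1:2])) stop("mask shape mismatch")
  out <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    tr <- cube$counts[idx[k, 1], idx[k, 2], ]
    if (sum(tr) < min_photons) next
    h <- decay_histogram(tr, period = cube$period,
                         bin_edges = cube$bin_edges)
    fit <- tryCatch(fit_mono(h, irf, options, min_photons = min_photons),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged)
      out[idx[k, 1], idx[k, 2]] <- fit$apparent_lifetime
  }
  class(out) <- c("lifetime_map", class(out))
  out
}

#' Render a FLIM image
#'
#' Two-dimensional lookup combining lifetime and intensity: hue encodes the
#' lifetime clipped to `display_range` (red = short, blue = long by
#' default), brightness encodes the normalized photon count; undefined
#' pixels are black.
#'
#' @param lifetime lifetime matrix (ns), `NA` = undefined.
#' @param intensity photon-count matrix, same shape.
#' @param display_range lifetime display limits `c(lo, hi)` (ns), `lo < hi`.
#' @param hue_range endpoints of the hue ramp (HSV hue in \[0,1\]).
#' @param normalization `"max"` or `"percentile"` (99th) intensity scaling.
#' @return `(rows, cols, 3)` RGB array in \[0,1\].
#' @export
render_flim <- function(lifetime, intensity, display_range = c(2.0, 3.0),
                        hue_range = c(0, 0.7),
                        normalization = c("max", "percentile")) {
  stopifnot(all(dim(lifetime) == dim(intensity)))
  if (display_range[1] >= display_range[2])
    stop("display_range must be increasing")
  normalization <- match.arg(normalization)
  top <- if (normalization == "max") max(intensity) else
    stats::quantile(intensity, 0.99)
  bright <- pmin(intensity / max(top, 1e-12), 1)
  frac <- (pmin(pmax(lifetime, display_range[1]), display_range[2]) -
             display_range[1]) / diff(display_range)
  hue <- hue_range[1] + frac * (hue_range[2] - hue_range[1])
  ok <- !is.na(lifetime)
  col <- matrix(0, length(lifetime), 3)
  if (any(ok)) {
    rgb01 <- grDevices::col2rgb(hsv(hue[ok], 1, bright[ok])) / 255
    col[ok, ] <- t(rgb01)
  }
  array(col, dim = c(dim(lifetime), 3))
}
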