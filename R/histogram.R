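#' TCSPC decay histogram
#'
#' Photon counts per arrival-time bin within one excitation period; the unit
#' of all decay fitting.
#'
#' @param counts non-negative integer photon counts per bin.
#' @param period excitation repetition period (ns).
#' @param bin_edges optional uniform bin edges (ns); defaults to
#'   `length(counts)` equal bins over `[0, period]`.
#' @return an object of class `decay_histogram` with fields `counts`,
#'   `bin_edges`, `period` and `n_photons`.
#' @export
decay_histogram <- function(counts, period, bin_edges = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  if (is.null(bin_edges)) bin_edges <- seq(0, period, length.out = n + 1L)
  stopifnot(length(bin_edges) == n + 1L)
  w <- diff(bin_edges)
  if (any(abs(w - w[1]) > 1e-12)) stop("bins must have uniform width")
  if (bin_edges[n + 1L] > period + 1e-9)
    stop("last bin edge exceeds the period")
  structure(list(counts = counts, bin_edges = as.numeric(bin_edges),
                 period = as.numeric(period), n_photons = sum(counts)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins over %.4g ns, %s photons\n",
              length(x$counts), x$period, format(x$n_photons, big.mark = ",")))
  invisible(x)
}

bin_centers <- function(hist_or_edges) {
  e <- if (inherits(hist_or_edges, "decay_histogram"))
    hist_or_edges$bin_edges else hist_or_edges
  (e[-length(e)] + e[-1L]) / 2
}

#' TCSPC image cube
#'
#' Per-pixel decay histograms arranged as a 3-D array (y, x, time bin),
#' plus acquisition metadata.
#'
#' @param counts 3-D non-negative array `(rows, cols, n_bins)`.
#' @param period excitation repetition period (ns).
#' @param bin_edges optional uniform bin edges (ns).
#' @param pixel_size_um optional pixel size (micrometres).
#' @param frequency_mhz pulse repetition frequency (MHz); defaults to
#'   `1000 / period`.
#' @return an object of class `tcspc_cube`.
#' @export
tcspc_cube <- function(counts, period, bin_edges = NULL,
                       pixel_size_um = NA_real_, frequency_mhz = NULL) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (any(counts < 0)) stop("counts must be non-negative")
  nb <- dim(counts)[3]
  if (is.null(bin_edges)) bin_edges <- seq(0, period, length.out = nb + 1L)
  stopifnot(length(bin_edges) == nb + 1L)
  structure(list(counts = counts, bin_edges = as.numeric(bin_edges),
                 period = as.numeric(period),
                 pixel_size_um = as.numeric(pixel_size_um),
                 frequency_mhz = as.numeric(frequency_mhz %||% (1000 / period))),
            class = "tcspc_cube")
}

#' @export
print.tcspc_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<tcspc_cube> %d x %d pixels, %d time bins over %.4g ns, %s photons\n",
    d[1], d[2], d[3], x$period, format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Photon-count intensity image of a cube
#'
#' @param cube a [tcspc_cube()].
#' @return matrix of per-pixel total photon counts.
#' @export
cube_intensity <- function(cube) {
  stopifnot(inherits(cube, "tcspc_cube"))
  rowSums(cube$counts, dims = 2L)
}

#' Pool pixel decays into one histogram
#'
#' Sums the decay traces of all pixels selected by `mask`, reproducing
#' whole-cell (or whole-region) pooled-photon analysis.
#'
#' @param cube a [tcspc_cube()].
#' @param mask logical matrix matching the cube's spatial dimensions.
#' @return a [decay_histogram()].
#' @export
pool_pixels <- function(cube, mask) {
  stopifnot(inherits(cube, "tcspc_cube"), is.logical(mask))
  d <- dim(cube$counts)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape does not match the cube's spatial dimensions")
  if (!any(mask)) stop("mask selects no pixels")
  flat <- matrix(cube$counts, d[1] * d[2], d[3])
  decay_histogram(colSums(flat[as.vector(mask), , drop = FALSE]),
                  period = cube$period, bin_edges = cube$bin_edges)
}
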