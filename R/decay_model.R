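#' Multi-exponential decay model
#'
#' Describes the emission-time distribution of detected photons within one
#' excitation period: a mixture of periodic exponential components plus a
#' uniform background. Component weights are amplitude fractions of unit-area
#' component profiles; together with the background fraction they sum to 1.
#'
#' @param lifetimes numeric vector of component lifetimes (ns), all > 0.
#' @param amplitudes numeric vector of amplitude fractions in \[0,1\], same
#'   length as `lifetimes`.
#' @param background uniform background fraction in \[0,1\].
#' @return an object of class `decay_model`.
#' @examples
#' # 81% FRET mixture of a 2.0 ns (FRET) and a 2.79 ns (no-FRET) component
#' decay_model(c(2.79, 2.0), c(0.19, 0.81))
#' @export
decay_model <- function(lifetimes, amplitudes, background = 0) {
  stopifnot(is.numeric(lifetimes), is.numeric(amplitudes),
            length(lifetimes) == length(amplitudes))
  if (length(lifetimes) == 0L)
    stop("decay_model needs at least one component")
  if (any(lifetimes <= 0))
    stop("all lifetimes must be > 0")
  if (any(amplitudes < -1e-9) || background < -1e-9)
    stop("amplitude and background fractions must be non-negative")
  tot <- sum(amplitudes) + background
  if (abs(tot - 1) > 1e-9)
    stop("amplitude fractions + background must sum to 1 (got ",
         format(tot), ")")
  structure(list(lifetimes = as.numeric(lifetimes),
                 amplitudes = as.numeric(amplitudes),
                 background = as.numeric(background)),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat("<decay_model>\n")
  for (i in seq_along(x$lifetimes))
    cat(sprintf("  component %d: tau = %.4g ns, amplitude = %.4g\n",
                i, x$lifetimes[i], x$amplitudes[i]))
  cat(sprintf("  background fraction: %.4g\n", x$background))
  invisible(x)
}

#' Gaussian instrument response function
#'
#' Parametric IRF used both to simulate photon timing jitter and as the
#' convolution kernel of the fitted decay model.
#'
#' @param center peak position (ns) of the IRF within the period.
#' @param fwhm full width at half maximum (ns), > 0.
#' @return an object of class `irf_model` with `kind = "gaussian"`.
#' @export
gaussian_irf <- function(center, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("fwhm must be a positive number")
  structure(list(kind = "gaussian", center = as.numeric(center),
                 fwhm = as.numeric(fwhm),
                 sd = as.numeric(fwhm) / (2 * sqrt(2 * log(2)))),
            class = "irf_model")
}

#' Empirical instrument response function
#'
#' An IRF given as a measured histogram over time bins; the profile is
#' normalized to unit mass and treated as piecewise-uniform within bins.
#'
#' @param profile non-negative counts or probabilities per bin.
#' @param bin_edges bin edges (ns), length `length(profile) + 1`, strictly
#'   increasing.
#' @return an object of class `irf_model` with `kind = "empirical"`.
#' @export
empirical_irf <- function(profile, bin_edges) {
  stopifnot(is.numeric(profile), is.numeric(bin_edges),
            length(bin_edges) == length(profile) + 1L)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (any(profile < 0)) stop("empirical IRF profile must be non-negative")
  s <- sum(profile)
  if (s <= 0) stop("empirical IRF profile must have positive mass")
  structure(list(kind = "empirical", profile = as.numeric(profile) / s,
                 bin_edges = as.numeric(bin_edges)),
            class = "irf_model")
}

#' Discretize an IRF onto histogram bins
#'
#' Returns the per-bin probability mass of the IRF over one period, with
#' Gaussian mass wrapped periodically (photons jittered past the period edge
#' fold into the next pulse). The profile sums to 1.
#'
#' @param irf an [gaussian_irf()] or [empirical_irf()] object.
#' @param bin_edges uniform bin edges (ns) spanning `[0, period]`.
#' @param period excitation repetition period (ns).
#' @return numeric vector of per-bin mass, length `length(bin_edges) - 1`.
#' @export
discretize_irf <- function(irf, bin_edges, period) {
  stopifnot(inherits(irf, "irf_model"))
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  n <- length(bin_edges) - 1L
  if (irf$kind == "gaussian") {
    # wrap enough periods to capture all Gaussian mass
    kmax <- max(1L, ceiling((irf$center + 6 * irf$sd) / period))
    kmin <- min(-1L, floor((irf$center - 6 * irf$sd) / period))
    p <- numeric(n)
    for (k in kmin:kmax) {
      lo <- pnorm(bin_edges[-(n + 1L)] + k * period, irf$center, irf$sd)
      hi <- pnorm(bin_edges[-1L] + k * period, irf$center, irf$sd)
      p <- p + (hi - lo)
    }
  } else {
    p <- rebin_profile(irf$profile, irf$bin_edges, bin_edges, period)
  }
  s <- sum(p)
  if (s <= 0) stop("IRF has no mass on the requested bins")
  p / s
}

# Rebin a piecewise-uniform profile from one (periodic) bin grid to another.
# Exact overlap integrals; source mass outside [0, period) wraps.
rebin_profile <- function(profile, src_edges, dst_edges, period) {
  nd <- length(dst_edges) - 1L
  out <- numeric(nd)
  ns <- length(profile)
  for (i in seq_len(ns)) {
    if (profile[i] == 0) next
    a <- src_edges[i] %% period
    w <- src_edges[i + 1L] - src_edges[i]
    b <- a + w
    dens <- profile[i] / w
    # split the (possibly wrapped) source interval at the period boundary
    segs <- if (b <= period) list(c(a, b)) else
      list(c(a, period), c(0, b - period))
    for (sg in segs) {
      lo <- pmax(dst_edges[-(nd + 1L)], sg[1])
      hi <- pmin(dst_edges[-1L], sg[2])
      ov <- pmax(hi - lo, 0)
      out <- out + dens * ov
    }
  }
  if (abs(sum(out) - sum(profile)) > 1e-6 * sum(profile))
    stop("IRF rebinning lost mass; bin grids are incompatible with the period")
  out
}

irf_mean <- function(irf, period) {
  if (irf$kind == "gaussian") irf$center %% period
  else {
    ctr <- (irf$bin_edges[-length(irf$bin_edges)] +
              irf$bin_edges[-1L]) / 2
    sum(irf$profile * (ctr %% period))
  }
}

# sample n photon delays (ns) from the IRF
sample_irf <- function(irf, n) {
  if (irf$kind == "gaussian") {
    rnorm(n, irf$center, irf$sd)
  } else {
    i <- sample.int(length(irf$profile), n, replace = TRUE,
                    prob = irf$profile)
    irf$bin_edges[i] + runif(n) * diff(irf$bin_edges)[i]
  }
}
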