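#' Decay-fit options
#'
#' @param objective `"mle"` (Poisson maximum likelihood, the default; photon
#'   counts are Poisson) or `"marquardt"` (Levenberg-Marquardt weighted least
#'   squares, mirroring classic TCSPC fitting software).
#' @param background include a free uniform background fraction.
#' @param fit_start start of the fit window (ns); earlier bins are excluded
#'   (useful when early-time IRF imperfections dominate the residuals).
#' @param restarts number of perturbed restarts on non-convergence.
#' @param reltol relative convergence tolerance.
#' @param maxit maximum iterations.
#' @return list of options.
#' @export
fit_options <- function(objective = c("mle", "marquardt"),
                        background = TRUE, fit_start = 0,
                        restarts = 3L, reltol = 1e-10, maxit = 500L) {
  list(objective = match.arg(objective), background = background,
       fit_start = fit_start, restarts = restarts, reltol = reltol,
       maxit = maxit)
}

#' Fit a mono-exponential decay
#'
#' Estimates the apparent fluorescence lifetime of a pooled decay histogram
#' by fitting a single IRF-convolved periodic exponential (plus optional
#' uniform background). The apparent lifetime of multi-component data from a
#' mono fit is the standard FLIM readout: FRET shortens it.
#'
#' @param hist a [decay_histogram()].
#' @param irf `irf_model` (or `NULL` for an ideal delta IRF).
#' @param options a [fit_options()] list.
#' @param min_photons reject histograms with fewer photons (default 1000).
#' @return a `fit_result` with `apparent_lifetime` (ns), `background`,
#'   `objective` value (Poisson deviance or weighted SSE), residual summary
#'   `max_rel_dev` (maximum relative model-data deviation among bins holding
#'   the top half of the counts), `converged`, `n_photons`.
#' @export
fit_mono <- function(hist, irf, options = fit_options(),
                     min_photons = 1000) {
  fd <- prepare_fit(hist, options, min_photons)
  tau0 <- init_tau(hist, irf)
  if (options$objective == "mle") {
    # 1-D search over log(tau); the background fraction enters the profile
    # linearly and is profiled out at each tau
    comp_fn <- function(tau) model_profile(tau, 1, 0, irf, hist, fd)
    obj <- function(lt) profile_bg_deviance(comp_fn(exp(lt)), fd,
                                            options$background)$value
    o <- optimize(obj, interval = log(c(0.05, 15)), tol = 1e-8)
    tau <- exp(o$minimum)
    inner <- profile_bg_deviance(comp_fn(tau), fd, options$background)
    res <- list(value = inner$value, converged = TRUE)
    bg <- inner$bg
  } else {
    profile_fn <- function(par) {
      tau <- exp(par[1])
      bg <- if (options$background) plogis(par[2]) else 0
      model_profile(tau, 1, bg, irf, hist, fd)
    }
    par0 <- c(log(tau0), if (options$background) qlogis(0.02))
    res <- robust_optim(profile_fn, par0, options, fd)
    tau <- exp(res$par[1])
    bg <- if (options$background) plogis(res$par[2]) else 0
  }
  p <- mix_bg(model_profile(tau, 1, 0, irf, hist, fd), bg)
  make_fit_result("mono", hist, fd, p,
                  apparent_lifetime = tau, background = bg,
                  objective = res$value, converged = res$converged)
}

#' Fit a fixed-lifetime bi-exponential decay and estimate %FRET
#'
#' Fits a two-component decay whose lifetimes are fixed to the no-FRET donor
#' lifetime (`tau_slow`, default 2.79 ns) and the full-FRET lifetime of the
#' donor-acceptor tandem reference (`tau_fast`, default 2.0 ns); only the
#' component amplitudes (and optional background) are free. The FRET
#' percentage is the fast amplitude over the total amplitude, clamped to
#' \[0, 100\].
#'
#' @inheritParams fit_mono
#' @param tau_slow,tau_fast fixed lifetimes (ns), `tau_slow > tau_fast > 0`.
#' @return a `fit_result` with `amplitude_fast`, `amplitude_slow`,
#'   `fixed_lifetimes`, `fret_percent`, `background`, `objective`,
#'   `converged`, `n_photons`.
#' @export
fit_biexp_fixed <- function(hist, irf, tau_slow = 2.79, tau_fast = 2.0,
                            options = fit_options(), min_photons = 1000) {
  if (!(tau_slow > tau_fast) || tau_fast <= 0)
    stop("require tau_slow > tau_fast > 0")
  fd <- prepare_fit(hist, options, min_photons)
  # fixed lifetimes: the two component profiles never change, so compute
  # them once and search only the amplitude mixture (background profiled)
  p_slow <- model_profile(tau_slow, 1, 0, irf, hist, fd)
  p_fast <- model_profile(tau_fast, 1, 0, irf, hist, fd)
  mix_fn <- function(a) (1 - a) * p_slow + a * p_fast
  if (options$objective == "mle") {
    obj <- function(a) profile_bg_deviance(mix_fn(a), fd,
                                           options$background)$value
    o <- optimize(obj, interval = c(0, 1), tol = 1e-9)
    # golden search cannot land exactly on a boundary optimum; test the ends
    cand <- c(o$minimum, 0, 1)
    vals <- vapply(cand, obj, 0)
    a <- cand[which.min(vals)]
    inner <- profile_bg_deviance(mix_fn(a), fd, options$background)
    res <- list(value = inner$value, converged = TRUE)
    bg <- inner$bg
  } else {
    profile_fn <- function(par) {
      a <- plogis(par[1])
      bg <- if (options$background) plogis(par[2]) else 0
      mix_bg(mix_fn(a), bg)
    }
    par0 <- c(qlogis(0.5), if (options$background) qlogis(0.02))
    res <- robust_optim(profile_fn, par0, options, fd)
    a <- plogis(res$par[1])
    bg <- if (options$background) plogis(res$par[2]) else 0
  }
  p <- mix_bg(mix_fn(a), bg)
  make_fit_result("biexp_fixed", hist, fd, p,
                  amplitude_fast = a * (1 - bg),
                  amplitude_slow = (1 - a) * (1 - bg),
                  fixed_lifetimes = c(slow = tau_slow, fast = tau_fast),
                  fret_percent = percent_fret(a, 1 - a),
                  background = bg, objective = res$value,
                  converged = res$converged)
}

#' FRET percentage from component amplitudes
#'
#' The amplitude of the fast (FRET) component over the total amplitude,
#' in percent: the fraction of donor molecules engaged in complex.
#'
#' @param amplitude_fast,amplitude_slow non-negative amplitudes, not both 0.
#' @return percentage in \[0, 100\].
#' @examples
#' percent_fret(0.81, 0.19)  # 81
#' @export
percent_fret <- function(amplitude_fast, amplitude_slow) {
  if (amplitude_fast < 0 || amplitude_slow < 0)
    stop("amplitudes must be non-negative")
  tot <- amplitude_fast + amplitude_slow
  if (tot == 0) stop("both amplitudes are zero; %FRET undefined")
  min(max(100 * amplitude_fast / tot, 0), 100)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s> ", x$model_kind))
  if (x$model_kind == "mono")
    cat(sprintf("apparent lifetime = %.4f ns", x$apparent_lifetime))
  else
    cat(sprintf("%%FRET = %.1f (A_fast %.3f / A_slow %.3f)",
                x$fret_percent, x$amplitude_fast, x$amplitude_slow))
  cat(sprintf(", background = %.3f, %s, n = %s\n", x$background,
              if (x$converged) "converged" else "NOT converged",
              format(x$n_photons, big.mark = ",")))
  invisible(x)
}

# ---- internals ------------------------------------------------------------

prepare_fit <- function(hist, options, min_photons) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (hist$n_photons < 1) stop("empty histogram")
  if (hist$n_photons < min_photons)
    stop("histogram has ", hist$n_photons, " photons; floor is ", min_photons)
  keep <- bin_centers(hist) >= options$fit_start
  if (!any(keep)) stop("fit window excludes all bins")
  list(keep = keep, counts = hist$counts[keep], n = sum(hist$counts[keep]))
}

model_profile <- function(lifetimes, amps, bg, irf, hist, fd) {
  m <- decay_model(lifetimes, amps * (1 - bg), background = bg)
  p <- expected_decay(m, irf, hist$period, hist$bin_edges)[fd$keep]
  p / sum(p)
}

mix_bg <- function(comp, bg) (1 - bg) * comp + bg / length(comp)

# minimum Poisson deviance over the background fraction for a fixed
# component profile (1-D inner problem, cheap vector operations only)
profile_bg_deviance <- function(comp, fd, background) {
  dev <- function(bg)
    -2 * sum(fd$counts * log(pmax(mix_bg(comp, bg), 1e-300)))
  if (!background) return(list(value = dev(0), bg = 0))
  o <- optimize(dev, interval = c(0, 0.6), tol = 1e-9)
  cand <- c(o$minimum, 0)
  vals <- c(o$objective, dev(0))
  i <- which.min(vals)
  list(value = vals[i], bg = cand[i])
}

fit_objective <- function(counts, p, n, objective) {
  if (objective == "mle") {
    # Poisson/multinomial deviance (C statistic up to a data-only constant)
    -2 * sum(counts * log(pmax(p, 1e-300)))
  } else {
    # Neyman weighted least squares
    sum((counts - n * p)^2 / pmax(counts, 1))
  }
}

# minimize the chosen objective over the transformed parameters; "marquardt"
# goes through Levenberg-Marquardt on Neyman-weighted residuals
robust_optim <- function(profile_fn, par0, options, fd) {
  obj <- function(par)
    fit_objective(fd$counts, profile_fn(par), fd$n, options$objective)
  run <- function(p0) {
    if (options$objective == "marquardt") {
      resid_fn <- function(par)
        (fd$counts - fd$n * profile_fn(par)) / sqrt(pmax(fd$counts, 1))
      o <- minpack.lm::nls.lm(p0, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = min(options$maxit, 1024L),
                                ftol = options$reltol))
      list(par = o$par, value = sum(o$fvec^2),
           convergence = if (o$info %in% 1:4) 0L else 1L)
    } else if (length(p0) == 1L) {
      optim(p0, obj, method = "Brent", lower = p0 - 8, upper = p0 + 8,
            control = list(maxit = options$maxit))
    } else {
      optim(p0, obj, method = "Nelder-Mead",
            control = list(reltol = options$reltol, maxit = options$maxit))
    }
  }
  best <- run(par0)
  tries <- 0L
  while (best$convergence != 0 && tries < options$restarts) {
    tries <- tries + 1L
    jitter <- par0 + 0.5 * tries * (-1)^(seq_along(par0) + tries)
    cand <- run(jitter)
    if (cand$value < best$value) best <- cand
  }
  list(par = best$par, value = best$value, converged = best$convergence == 0)
}

# moment initializer: mean arrival time minus IRF centroid, wrap-corrected
init_tau <- function(hist, irf) {
  tc <- bin_centers(hist)
  mu <- sum(hist$counts * tc) / max(hist$n_photons, 1)
  off <- if (is.null(irf)) 0 else irf_mean(irf, hist$period)
  min(max(mu - off, 0.2), 10)
}

make_fit_result <- function(kind, hist, fd, p, ...) {
  # residual summary over well-populated bins: relative model-data deviation
  exp_counts <- fd$n * p
  big <- exp_counts >= stats::quantile(exp_counts, 0.5)
  max_rel_dev <- max(abs(fd$counts[big] - exp_counts[big]) /
                       pmax(exp_counts[big], 1))
  structure(c(list(model_kind = kind, n_photons = hist$n_photons,
                   max_rel_dev = max_rel_dev), list(...)),
            class = "fit_result")
}
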