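# shared fixtures for the suite: small, fast, fully seeded

DEFAULT_IRF <- gaussian_irf(0.5, 0.2)
NEAR_DELTA_IRF <- gaussian_irf(0.0125, 1e-6)  # all mass in the first bin

edges_ns <- function(n_bins = 500L, period = 12.5)
  seq(0, period, length.out = n_bins + 1L)

donor_model <- function(background = 0.01)
  decay_model(2.79, 1 - background, background)

mixture_model <- function(f, background = 0.01,
                          tau_slow = 2.79, tau_fast = 2.0)
  decay_model(c(tau_slow, tau_fast),
              c(1 - f, f) * (1 - background), background)

# noiseless "histogram": expected profile scaled to a large photon count
noiseless_hist <- function(model, irf, n = 1e6, n_bins = 500L,
                           period = 12.5) {
  p <- expected_decay(model, irf, period, edges_ns(n_bins, period))
  decay_histogram(p * n, period = period)
}

small_geometry <- function(size = 48L)
  cell_geometry(size = size, cell_axes = c(19, 15), nucleus_axes = c(7, 5),
                seed = 1L)

# independent grid-search MLE oracles (brute force over the same deviance)
grid_mle_tau <- function(hist, irf, taus = seq(1.5, 3.5, by = 0.001)) {
  fd <- list(keep = rep(TRUE, length(hist$counts)), counts = hist$counts,
             n = hist$n_photons)
  dev <- vapply(taus, function(tau) {
    p <- expected_decay(decay_model(tau, 1), irf, hist$period,
                        hist$bin_edges)
    bgfit <- optimize(function(bg) {
      q <- (1 - bg) * p + bg / length(p)
      -2 * sum(hist$counts * log(pmax(q, 1e-300)))
    }, c(0, 0.6), tol = 1e-9)
    bgfit$objective
  }, 0)
  taus[which.min(dev)]
}

grid_mle_afast <- function(hist, irf, tau_slow = 2.79, tau_fast = 2.0,
                           grid = seq(0, 1, by = 0.001)) {
  ps <- expected_decay(decay_model(tau_slow, 1), irf, hist$period,
                       hist$bin_edges)
  pf <- expected_decay(decay_model(tau_fast, 1), irf, hist$period,
                       hist$bin_edges)
  dev <- vapply(grid, function(a) {
    p <- (1 - a) * ps + a * pf
    bgfit <- optimize(function(bg) {
      q <- (1 - bg) * p + bg / length(p)
      -2 * sum(hist$counts * log(pmax(q, 1e-300)))
    }, c(0, 0.6), tol = 1e-9)
    bgfit$objective
  }, 0)
  grid[which.min(dev)]
}
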