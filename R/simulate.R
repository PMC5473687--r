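#' Simulate a TCSPC decay histogram
#'
#' Draws individual photon arrival times: each photon is an IRF timing draw
#' plus an exponential emission delay from a component chosen by amplitude
#' fraction (or a uniform draw for background photons), wrapped modulo the
#' excitation period and binned. Photon count is conserved exactly and the
#' result is reproducible for a given seed.
#'
#' @param model a [decay_model()].
#' @param irf an `irf_model`, or `NULL` for an ideal delta IRF at t = 0.
#' @param n_photons number of photons to record (>= 1).
#' @param period excitation repetition period (ns); default 12.5 (80 MHz).
#' @param n_bins number of time bins; default 500 (25 ps bins at 12.5 ns).
#' @param seed integer seed.
#' @return a [decay_histogram()].
#' @export
simulate_decay_histogram <- function(model, irf, n_photons,
                                     period = 12.5, n_bins = 500L,
                                     seed = 1L) {
  stopifnot(inherits(model, "decay_model"), n_photons >= 1, period > 0)
  if (period < 3 * max(model$lifetimes))
    warning("period is shorter than 3x the longest lifetime; ",
            "wrap-around will be heavy")
  edges <- seq(0, period, length.out = n_bins + 1L)
  counts <- with_seed(seed, {
    t <- sample_photon_times(model, irf, n_photons, period)
    tabulate(pmin(floor(t / (period / n_bins)) + 1L, n_bins), nbins = n_bins)
  })
  decay_histogram(counts, period = period, bin_edges = edges)
}

# vectorized photon arrival sampler (times in [0, period))
sample_photon_times <- function(model, irf, n, period) {
  k <- length(model$lifetimes)
  probs <- c(model$amplitudes, model$background)
  comp <- sample.int(k + 1L, n, replace = TRUE, prob = probs)
  t <- numeric(n)
  bg <- comp == k + 1L
  if (any(bg)) t[bg] <- runif(sum(bg), 0, period)
  for (i in seq_len(k)) {
    sel <- comp == i
    ni <- sum(sel)
    if (ni == 0L) next
    d <- if (is.null(irf)) 0 else sample_irf(irf, ni)
    t[sel] <- d + rexp(ni, rate = 1 / model$lifetimes[i])
  }
  t %% period
}

#' FRET condition presets
#'
#' Named presets describing the simulated expression conditions: the
#' saturating acceptor-to-FRET link (`fmax`, half-saturation `k_sat`) and the
#' spatial FRET offsets of the plasma-membrane ring and endosomal puncta
#' relative to the cytoplasmic baseline. `stx3_vamp3`-type conditions place
#' extra FRET at the membrane; `stx3_vamp8` places it on intracellular
#' puncta instead.
#'
#' @param condition preset name; one of `donor_only`, `tandem`,
#'   `stx3_vamp3`, `stx3_vamp8`, `stx4_vamp3`, `stx4_vamp3_lps`,
#'   `vamp3_d71`, `fkbp_frb_dimerizer`.
#' @return list of preset parameters.
#' @export
fret_preset <- function(condition) {
  presets <- list(
    donor_only        = list(fmax = 0.00, k_sat = 1, dm = 0.00, de = 0.00),
    tandem            = list(fmax = 1.00, k_sat = 0, dm = 0.00, de = 0.00),
    stx3_vamp3        = list(fmax = 0.80, k_sat = 1, dm = 0.07, de = 0.00),
    stx3_vamp8        = list(fmax = 0.60, k_sat = 1, dm = -0.05, de = 0.15),
    stx4_vamp3        = list(fmax = 0.30, k_sat = 1, dm = 0.03, de = 0.00),
    stx4_vamp3_lps    = list(fmax = 0.55, k_sat = 1, dm = 0.06, de = 0.00),
    vamp3_d71         = list(fmax = 0.35, k_sat = 1, dm = 0.03, de = 0.00),
    fkbp_frb_dimerizer = list(fmax = 0.90, k_sat = 0.5, dm = 0.04, de = 0.00)
  )
  p <- presets[[condition]]
  if (is.null(p)) stop("unknown condition preset: ", condition)
  c(list(condition = condition), p)
}

#' Saturating acceptor-to-FRET link
#'
#' Mean FRET fraction of a cell as a function of its acceptor expression
#' level: `F = fmax * I / (I + k_sat)`, reproducing FRET that rises with
#' acceptor availability and saturates near `fmax` at high expression.
#'
#' @param intensity acceptor intensity (arbitrary units, >= 0).
#' @param fmax saturating FRET fraction.
#' @param k_sat half-saturation intensity; 0 gives `fmax` everywhere.
#' @return FRET fraction(s) in \[0, 1\].
#' @export
acceptor_fret_link <- function(intensity, fmax, k_sat) {
  if (k_sat <= 0) return(rep(fmax, length(intensity)))
  fmax * intensity / (intensity + k_sat)
}

#' Synthetic cell geometry
#'
#' Elliptical cell with an elliptical nucleus hole, a plasma-membrane ring of
#' given width, and circular endosomal puncta placed uniformly in the
#' cytoplasm. The analyzed cell mask excludes the nucleus.
#'
#' @param size image side length (pixels).
#' @param cell_axes ellipse semi-axes (pixels) of the cell outline.
#' @param nucleus_axes semi-axes of the nucleus.
#' @param ring_width membrane ring width (pixels).
#' @param n_endosomes number of endosomal puncta.
#' @param endosome_radius punctum radius (pixels).
#' @param seed integer seed for endosome placement.
#' @return list of logical masks `cell`, `nucleus`, `membrane`, `interior`,
#'   `endosomes`, class `cell_geometry`.
#' @export
cell_geometry <- function(size = 64L, cell_axes = c(26, 20),
                          nucleus_axes = c(9, 7), ring_width = 2L,
                          n_endosomes = 8L, endosome_radius = 2L,
                          seed = 1L) {
  cx <- (size + 1) / 2
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  ell <- function(ax) ((yy - cx) / ax[1])^2 + ((xx - cx) / ax[2])^2 <= 1
  cell_full <- ell(cell_axes)
  nucleus <- ell(nucleus_axes)
  # membrane ring = outline band of the cell by disc erosion, so that the
  # simulated band coincides with the band an erosion-based region split
  # of the same depth recovers
  ring <- cell_full & !erode_mask(cell_full, ring_width)
  cell <- cell_full & !nucleus
  interior <- cell & !ring
  endo <- matrix(FALSE, size, size)
  if (n_endosomes > 0) {
    cand <- which(interior & !nucleus, arr.ind = TRUE)
    idx <- with_seed(seed,
      cand[sample.int(nrow(cand), min(n_endosomes, nrow(cand))), ,
           drop = FALSE])
    for (i in seq_len(nrow(idx))) {
      endo <- endo | (((yy - idx[i, 1])^2 + (xx - idx[i, 2])^2) <=
                        endosome_radius^2)
    }
    endo <- endo & interior
  }
  structure(list(size = size, cell = cell, nucleus = nucleus,
                 membrane = ring, interior = interior, endosomes = endo),
            class = "cell_geometry")
}

#' Simulate one cell
#'
#' Generates a TCSPC image cube (or, with `spatial = FALSE`, a pooled
#' whole-cell histogram) for one cell under a condition preset. The cell's
#' mean FRET fraction follows the saturating acceptor link from a log-normal
#' acceptor intensity draw; the per-pixel FRET map adds the preset's
#' membrane/endosome offsets; photons are distributed over pixels in
#' proportion to the donor intensity map.
#'
#' @param geometry a [cell_geometry()] (ignored when `spatial = FALSE`).
#' @param condition preset label, see [fret_preset()].
#' @param photon_budget total photons for the cell (study-scale default
#'   750,000; floor 50,000 in acquisition terms, not enforced here).
#' @param seed integer seed.
#' @param tau_slow,tau_fast donor no-FRET and full-FRET lifetimes (ns).
#' @param background uniform background photon fraction.
#' @param period,n_bins histogram layout.
#' @param irf `irf_model` used for photon timing.
#' @param acceptor_intensity optional fixed acceptor intensity (a.u.);
#'   drawn log-normally (meanlog 0, sdlog 0.8) when `NULL`.
#' @param acceptor_blob_contrast relative acceptor excess of a juxtanuclear
#'   blob (0 = uniform acceptor map).
#' @param membrane_brightness donor intensity multiplier of the membrane ring.
#' @param spatial simulate a full image cube (`TRUE`) or a pooled whole-cell
#'   histogram only.
#' @return list with elements `cube` (or `histogram`), `geometry`,
#'   `acceptor_map`, and `truth` (per-pixel FRET map where spatial, plus the
#'   per-cell truth row: condition, acceptor intensity, mean FRET fraction,
#'   photon budget, seed).
#' @export
simulate_cell <- function(geometry, condition, photon_budget = 750000,
                          seed = 1L, tau_slow = 2.79, tau_fast = 2.0,
                          background = 0.01, period = 12.5, n_bins = 500L,
                          irf = gaussian_irf(0.5, 0.2),
                          acceptor_intensity = NULL,
                          acceptor_blob_contrast = 0,
                          membrane_brightness = 1,
                          spatial = TRUE) {
  preset <- fret_preset(condition)
  if (photon_budget < 1) stop("photon_budget must be positive")
  acc <- acceptor_intensity %||%
    with_seed(derive_seed(seed, 1L), rlnorm(1, 0, 0.8))
  f_cell <- acceptor_fret_link(acc, preset$fmax, preset$k_sat)

  if (!spatial) {
    model <- fret_mixture_model(f_cell, tau_slow, tau_fast, background)
    h <- simulate_decay_histogram(model, irf, photon_budget, period, n_bins,
                                  seed = derive_seed(seed, 2L))
    truth <- data.frame(condition = condition, acceptor_intensity = acc,
                        fret_fraction = f_cell,
                        photon_budget = photon_budget, seed = seed)
    return(list(histogram = h, truth = truth))
  }

  stopifnot(inherits(geometry, "cell_geometry"))
  fmap <- matrix(0, geometry$size, geometry$size)
  fmap[geometry$cell] <- f_cell
  fmap[geometry$membrane] <- f_cell + preset$dm
  fmap[geometry$endosomes] <- f_cell + preset$de
  fmap <- pmin(pmax(fmap, 0), 1)
  fmap[!geometry$cell] <- 0

  # donor expression texture (smooth hotspots) is shared by both channels:
  # in a tandem construct donor and acceptor sit on the same molecule, and
  # the blob factor models the acceptor-only juxtanuclear excess
  texture <- expression_texture(geometry, seed = derive_seed(seed, 4L))
  donor <- matrix(0, geometry$size, geometry$size)
  donor[geometry$cell] <- texture[geometry$cell]
  donor[geometry$membrane] <- donor[geometry$membrane] * membrane_brightness

  blob <- juxtanuclear_blob(geometry)
  acc_map <- donor * acc * (1 + acceptor_blob_contrast * blob)

  cube <- with_seed(derive_seed(seed, 2L), {
    pix <- which(geometry$cell)
    np <- as.vector(rmultinom_large(photon_budget, donor[pix]))
    counts <- array(0, dim = c(geometry$size, geometry$size, n_bins))
    # expand per-photon pixel assignment, then draw component/time per photon
    ppix <- rep.int(pix, np)
    f <- fmap[ppix]
    nb <- length(ppix)
    u <- runif(nb)
    is_bg <- u < background
    is_fast <- !is_bg & (u < background + (1 - background) * f)
    t <- numeric(nb)
    t[is_bg] <- runif(sum(is_bg), 0, period)
    for (sel_tau in list(c(TRUE, tau_fast), c(FALSE, tau_slow))) {
      sel <- if (sel_tau[1]) is_fast else (!is_bg & !is_fast)
      ni <- sum(sel)
      if (ni > 0)
        t[sel] <- sample_irf(irf, ni) + rexp(ni, 1 / sel_tau[2])
    }
    t <- t %% period
    tb <- pmin(floor(t / (period / n_bins)) + 1L, n_bins)
    idx <- ppix + (tb - 1L) * geometry$size^2
    tab <- tabulate(idx, nbins = geometry$size^2 * n_bins)
    counts[] <- tab
    counts
  })

  truth <- data.frame(condition = condition, acceptor_intensity = acc,
                      fret_fraction = sum(fmap * donor) / sum(donor),
                      photon_budget = photon_budget, seed = seed)
  list(cube = tcspc_cube(cube, period = period), geometry = geometry,
       acceptor_map = acc_map, fret_map = fmap, truth = truth)
}

# decay model for a cell with FRET fraction f (amplitude convention)
fret_mixture_model <- function(f, tau_slow, tau_fast, background) {
  decay_model(c(tau_slow, tau_fast),
              c((1 - f) * (1 - background), f * (1 - background)),
              background = background)
}

# multinomial draw robust to large n
rmultinom_large <- function(n, prob) {
  stats::rmultinom(1, n, prob)
}

# smooth multiplicative expression texture over the cell: a few seeded
# Gaussian hotspots on a uniform base
expression_texture <- function(geometry, seed, n_spots = 3L,
                               amplitude = 0.8, width = 36) {
  size <- geometry$size
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  cand <- which(geometry$cell, arr.ind = TRUE)
  ctr <- with_seed(seed,
    cand[sample.int(nrow(cand), min(n_spots, nrow(cand))), , drop = FALSE])
  tex <- matrix(1, size, size)
  for (i in seq_len(nrow(ctr)))
    tex <- tex + amplitude *
      exp(-((yy - ctr[i, 1])^2 + (xx - ctr[i, 2])^2) / (2 * width))
  tex
}

# smooth blob next to the nucleus (acceptor maturation excess)
juxtanuclear_blob <- function(geometry) {
  size <- geometry$size
  cx <- (size + 1) / 2
  nuc <- which(geometry$nucleus, arr.ind = TRUE)
  r_nuc <- if (nrow(nuc)) max(abs(nuc[, 1] - cx)) else 4
  by <- cx
  bx <- cx + r_nuc + 4
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  b <- exp(-(((yy - by)^2 + (xx - bx)^2) / (2 * 16)))
  b * geometry$cell
}

#' Simulate a cell cohort
#'
#' Deterministically generates a population of cells across donors and
#' conditions, with optional per-donor random effects on the saturating FRET
#' amplitude, returning the cells plus a ground-truth table (one row per
#' cell) for recovery tests.
#'
#' @param config list with elements `conditions` (character vector),
#'   `cells_per_donor`, `donors`, `photon_budget`, and optionally
#'   `donor_sd` (SD of a per-donor multiplicative effect on the FRET
#'   fraction), `spatial`, `n_bins`, `geometry` arguments, and any
#'   [simulate_cell()] argument.
#' @param seed integer master seed.
#' @return list with `cells` (list of [simulate_cell()] results) and
#'   `truth` (data.frame: cell, donor, condition, acceptor_intensity,
#'   fret_fraction, photon_budget).
#' @export
simulate_cohort <- function(config, seed = 1L) {
  conditions <- config$conditions %||% "donor_only"
  donors <- config$donors %||% 4L
  cpd <- config$cells_per_donor %||% 10L
  budget <- config$photon_budget %||% 750000
  donor_sd <- config$donor_sd %||% 0
  spatial <- config$spatial %||% FALSE
  extra <- config[setdiff(names(config),
                          c("conditions", "donors", "cells_per_donor",
                            "photon_budget", "donor_sd", "spatial",
                            "geometry"))]
  geometry <- config$geometry %||%
    (if (spatial) cell_geometry() else NULL)
  cells <- list()
  rows <- list()
  idx <- 0L
  donor_eff <- with_seed(derive_seed(seed, 9999L),
                         exp(rnorm(donors, 0, donor_sd)))
  for (cond in conditions) for (d in seq_len(donors)) for (j in seq_len(cpd)) {
    idx <- idx + 1L
    cseed <- derive_seed(seed, idx)
    args <- c(list(geometry = geometry, condition = cond,
                   photon_budget = budget, seed = cseed, spatial = spatial),
              extra)
    cell <- do.call(simulate_cell, args)
    # per-donor multiplicative effect on the FRET fraction (recorded in truth)
    if (donor_sd > 0 && !spatial) {
      f <- min(cell$truth$fret_fraction * donor_eff[d], 1)
      args$acceptor_intensity <- cell$truth$acceptor_intensity
      model_f <- f
      cell$histogram <- simulate_decay_histogram(
        fret_mixture_model(model_f, args$tau_slow %||% 2.79,
                           args$tau_fast %||% 2.0,
                           args$background %||% 0.01),
        args$irf %||% gaussian_irf(0.5, 0.2), budget,
        args$period %||% 12.5, args$n_bins %||% 500L,
        seed = derive_seed(cseed, 3L))
      cell$truth$fret_fraction <- f
    }
    rows[[idx]] <- cbind(data.frame(cell = idx, donor = d), cell$truth)
    cells[[idx]] <- cell
  }
  truth <- if (idx > 0) do.call(rbind, rows) else
    data.frame(cell = integer(), donor = integer(), condition = character(),
               acceptor_intensity = numeric(), fret_fraction = numeric(),
               photon_budget = numeric(), seed = integer())
  list(cells = cells, truth = truth)
}
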