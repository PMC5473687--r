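# flimfret

FRET–FLIM analysis of time-correlated single photon counting (TCSPC) data
in R, for experiments that read out protein–protein interaction — such as
SNARE complex formation in live dendritic cells — through quenching of a
donor fluorophore's fluorescence lifetime.

When a donor (e.g. mCitrine on one SNARE) sits within Förster distance of an
acceptor (mCherry on its partner), energy transfer shortens the donor's
excited-state lifetime. The package covers the full analysis chain around
that physical readout:

- **Decay models and fitting.** Photon arrival-time histograms over one
  excitation period (default 12.5 ns, 80 MHz) are fitted with exponential
  decays convolved with the instrument response function (IRF), by Poisson
  maximum likelihood (default) or Levenberg–Marquardt least squares. The
  mono-exponential fit yields the *apparent lifetime* τ of a cell or region;
  the bi-exponential fit with *fixed* lifetimes

  I(t) ∝ (1 − A_fast)·e^(−t/τ_slow) + A_fast·e^(−t/τ_fast),
  τ_slow = 2.79 ns (donor only, no FRET), τ_fast = 2.0 ns (tandem
  donor–acceptor, 100 % FRET)

  estimates the FRET percentage as the amplitude fraction
  %FRET = 100·A_fast/(A_fast + A_slow), i.e. the fraction of donor molecules
  in complex. Periodic (wrap-around) excitation is handled exactly via the
  folded exponential / folded ex-Gaussian closed forms.
- **Phasor analysis.** First-harmonic (g, s) projections with reference-dye
  calibration (e.g. rhodamine B, 2.32 ns), semicircle/chord diagnostics and
  phase/modulation lifetime inversion.
- **FLIM maps.** Circular spatial binning (radius 3 → the classic 7×7
  29-pixel disc), intensity thresholding (15–100 % of maximum), per-pixel
  mono-exponential fitting, and lifetime×intensity rendering.
- **Cell-level statistics.** Periphery-vs-interior paired lifetimes from
  erosion-derived (or manual) region masks, OLS regressions of lifetime on
  acceptor expression and on %FRET, one-way ANOVA with Bonferroni-corrected
  relevant pairs, paired t-tests, and Pearson colocalization.
- **Synthetic microscope.** A seeded generator producing photon histograms,
  per-pixel decay cubes, masks and ground truth for cells whose FRET fraction
  follows a saturating function of acceptor expression, with
  condition presets that place the FRET contrast at the plasma membrane
  (e.g. `stx3_vamp3`) or on intracellular puncta (`stx3_vamp8`).
- **I/O.** A minimal PicoQuant PT3 (T3 mode) photon-record codec with
  overflow/marker handling, lossless TIFF+JSON containers for decay cubes
  and lifetime/intensity maps, and a fixed-header CSV cell table.

## Worked example

```r
library(flimfret)

irf <- gaussian_irf(center = 0.5, fwhm = 0.2)          # ns

# a cell in which 81% of donors are in complex, 750k photons
h <- simulate_decay_histogram(
  decay_model(c(2.79, 2.0), c(0.19, 0.81) * 0.99, background = 0.01),
  irf, n_photons = 750000, seed = 7)

fit_mono(h, irf)
#> <fit_result: mono> apparent lifetime = 2.1131 ns, background = 0.016, converged, n = 750,000

fit_biexp_fixed(h, irf, tau_slow = 2.79, tau_fast = 2.0)
#> <fit_result: biexp_fixed> %FRET = 81.3 (A_fast 0.804 / A_slow 0.185), background = 0.010, converged, n = 750,000
```

The mono fit reports the FRET-shortened apparent lifetime (2.11 ns, between
the 2.0 ns full-FRET and 2.79 ns no-FRET references); the fixed-lifetime
bi-exponential fit recovers the simulated 81 % complexed fraction from the
amplitudes alone.

Spatial analysis of a simulated cell with extra membrane FRET
(ΔF = 0.07 above the cytoplasm):

```r
geom <- cell_geometry(size = 64)
cell <- simulate_cell(geom, "stx3_vamp3", photon_budget = 750000,
                      seed = 5, acceptor_intensity = 1)
masks <- split_periphery_interior(geom$cell, depth = 2)
region_lifetime_pair(cell$cube, masks, irf)
#>    tau_P    tau_I
#> 2.353211 2.400115
```

The periphery is quenched by ≈ 47 ps relative to the interior — the
amplitude-weighted prediction ΔF·(τ_slow − τ_fast) = 0.07 × 0.79 ns.

An end-to-end cohort analysis (simulate → fit → regressions → group stats →
phasors, all written to a directory with the exact config used) is
`run_report()`; a thin command-line front end with `simulate`, `fit`,
`phasor`, `map`, `regions`, `stats` and `report` subcommands is installed at
`inst/scripts/flimpipe.R`.

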