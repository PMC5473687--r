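---
title: "Models and methods: FRET-FLIM analysis with flimfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: FRET-FLIM analysis with flimfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfret)
```

## The measurement model

In TCSPC FLIM, each detected photon is timed relative to the excitation
pulse. For a donor fluorophore with excited-state lifetime $\tau$, the
emission delay is exponential with mean $\tau$; the measured arrival time
adds the instrument's timing jitter (the IRF) and is folded into one
repetition period $T$ (default $T = 12.5$ ns, 80 MHz pulsing). FRET opens a
non-radiative decay channel, so a donor in complex with an acceptor emits
with a shorter lifetime; a cell containing both free and complexed donors
produces a mixture decay.

`flimfret` represents a decay as

$$p(t) \;=\; \sum_i A_i \, f_{\tau_i}(t) \;+\; \frac{b}{T},
\qquad t \in [0, T),$$

where $f_\tau$ is the *unit-area periodic* exponential (or its IRF
convolution), $A_i$ are amplitude fractions and $b$ a uniform background
fraction, with $\sum_i A_i + b = 1$. Because each component is normalized
to unit area, the amplitude fraction equals the fraction of photons a
component contributes, and the fixed-lifetime two-component fit below
recovers the mixing fraction directly. This one convention is used
consistently by the simulator and every estimator in the package.

Two estimators implement the standard FLIM readouts:

* **Apparent lifetime** — `fit_mono()` fits a single $\tau$ (plus optional
  background). For mixture data the mono-fit $\tau$ is the usual
  FRET-shortened "apparent lifetime"; it is bracketed by the
  amplitude-weighted and intensity-weighted mean lifetimes of the mixture.
* **%FRET** — `fit_biexp_fixed()` fixes the two lifetimes at the
  experimental references (no-FRET donor 2.79 ns; donor–acceptor tandem,
  100 % FRET, 2.0 ns) and frees only the amplitudes, since free-lifetime
  bi-exponential fits are ill-conditioned at realistic photon counts: small
  lifetime errors trade against large amplitude errors. The FRET percentage
  is $100\,A_{fast}/(A_{fast}+A_{slow})$ — the complexed fraction of donor
  molecules.

Both default lifetimes, the period, the IRF and the background treatment
are arguments, not constants.

### Exact periodic convolution

Fitting accuracy at the few-picosecond level requires that the fitted model
be the exact sampling distribution of the data. For a Gaussian IRF
(center $\mu$, width $\sigma$) the per-bin probabilities are computed from
the closed-form CDF of the exponentially modified Gaussian, summed over
wrapped periods:

$$F(x) = \Phi(z) - e^{\sigma^2/2\tau^2 - (x-\mu)/\tau}\,
\Phi(z - \sigma/\tau), \qquad z = (x-\mu)/\sigma,$$

evaluated on the log scale to avoid overflow. No discretized convolution is
involved, so there is no grid bias. Empirical (measured-histogram) IRFs are
treated as piecewise-uniform and applied by discrete circular convolution
with a half-bin phase correction — second-order accurate in the bin width.
Deep-tail bins of the folded exponential are computed as direct exponent
differences to preserve relative precision (CDF differencing cancels
catastrophically beyond ~30 lifetimes).

### Objectives and optimization

Photon counts are Poisson, so the default objective is the Poisson deviance
(MLE); a `"marquardt"` option minimizes Neyman-weighted least squares via
Levenberg–Marquardt (`minpack.lm`), mirroring the classic TCSPC fitting
tools. For the MLE the problem is reduced to fast 1-D searches: the
background enters the bin probabilities linearly and is profiled out at
each candidate $\tau$ (or amplitude), and in the fixed-lifetime fit the two
component profiles are computed once per histogram. Golden-section search
cannot terminate exactly on a boundary, so the amplitude fit explicitly
compares the interior optimum against $A_{fast} \in \{0, 1\}$; reported
%FRET is clamped to $[0, 100]$. Tolerances: $10^{-8}$ on $\log\tau$,
$10^{-9}$ on amplitudes and background. The test suite verifies the
optimizer against brute-force grid searches (0.001 ns / 0.001 amplitude
steps) on randomized instances.

The mono fit can exclude early bins (`fit_start`) where real instruments
show IRF imperfections; this is an option, not the default, because the
synthetic IRF has no such artifacts. Fit results retain a residual summary
(maximum relative model–data deviation over the well-populated bins) so
fit quality can be reported per cell.

## Phasor analysis

`phasor_transform()` projects a histogram onto the first harmonic of the
repetition frequency, $g = \langle\cos n\omega t\rangle$,
$s = \langle\sin n\omega t\rangle$, using bin centers (second-order
accurate). Mono-exponential decays lie on the universal semicircle
$(g-\tfrac12)^2 + s^2 = \tfrac14$; mixtures lie on chords, and the phase
and modulation lifetimes split apart there. The IRF multiplies every
phasor by the same complex factor, so a single reference measurement (a
dye of known lifetime, e.g. rhodamine B at 2.32 ns) yields a
modulation-ratio/phase-offset calibration that transfers exactly to any
other decay acquired with the same IRF — this is the standard
reference-based calibration route, and the transfer property is what the
tests assert.

## Pixel-wise FLIM maps

The imaging chain is: circular binning → intensity threshold →
per-pixel mono fit → lifetime×intensity rendering.

* "7 × 7 circular binning" is interpreted as the Euclidean-radius-3 disc —
  the 29 integer offsets with $dx^2+dy^2 \le 9$, the only disc that fills a
  7×7 window. Binning is an exact integer shift-and-add (an FFT
  convolution would break exact integer equality), truncated at borders.
* The intensity threshold keeps pixels between `low` and `high` fractions
  of the *maximum* binned intensity (15–100 % by default). Whether such
  thresholds reference the maximum or a percentile varies between tools;
  maximum is used here and exposed as an argument.
* Pixels need 100 photons after binning (below that, mono fits destabilize);
  failed or sub-floor pixels are `NA` and render black. Rendering maps
  lifetime to hue over a display range and photon counts to brightness;
  the colormap is configurable rather than matched to any vendor's.

## The synthetic microscope

`simulate_cell()`/`simulate_cohort()` generate the data the analysis
assumes, photon by photon: a component is chosen by amplitude fraction, an
IRF jitter and an exponential delay are drawn, and the sum is wrapped and
binned — so simulated histograms follow exactly the model the fitters use.
What is emulated, and the defaults chosen where the underlying experiment
leaves them open:

* **Geometry** — an elliptical cell with an elliptical nucleus hole, a
  2-pixel membrane ring and Poisson-placed endosomal puncta (64×64 pixels
  by default): the minimal geometry exposing a periphery/interior
  contrast. The ring is defined by disc erosion of the cell outline so
  that an erosion-based region split of the same depth recovers the same
  band.
* **FRET fractions** — each cell draws a log-normal acceptor intensity
  (meanlog 0, sdlog 0.8) and maps it through the saturating link
  $F = F_{max} I/(I+K)$; condition presets set $F_{max}$, $K$ and the
  spatial offsets (`stx3_vamp3`: membrane $+0.07$; `stx3_vamp8`: endosomes
  $+0.15$, membrane $-0.05$; a tandem preset with $F \equiv 1$; donor-only
  with $F \equiv 0$; further presets for weaker, stimulus-enhanced,
  fusion-deficient and dimerizer-forced interactions). The membrane offset
  of 0.07 makes the amplitude-weighted periphery−interior lifetime
  difference $\Delta F\,(\tau_{slow}-\tau_{fast}) \approx 55$ ps, the
  scale of the quenching the method is meant to localize.
* **Photon budgets** — 750,000 photons per cell by default (typical
  whole-cell recordings; 50,000 is a practical floor).
* **Timing** — 500 bins of 25 ps per 12.5 ns period (PicoHarp-class
  resolution); 1 % uniform background, since real TCSPC always has
  dark/ambient counts and the fitters must tolerate them.
* **Expression texture** — both channels share smooth seeded expression
  hotspots (the donor and acceptor of a tandem construct are the same
  molecule), and an optional juxtanuclear acceptor-excess blob emulates
  differential fluorophore maturation; raising its contrast lowers the
  whole-cell Pearson colocalization monotonically.
* **Donor effects** — optional per-donor multiplicative random effects on
  the FRET fraction, recorded in the truth table.

Everything is seeded; identical seeds give bit-identical cubes, and
per-cell sub-seeds are derived with 31-bit modular arithmetic.

What the generator deliberately does *not* model: anisotropy, detector
afterpulsing, pile-up, autofluorescence, optical sectioning, or biological
variation beyond the acceptor-expression and donor effects above.
Passing recovery tests on these simulations therefore demonstrates the
*estimators'* correctness under the stated noise model, not robustness to
every instrument artifact of a real microscope.

## Region statistics and cohort analyses

`split_periphery_interior()` automates the periphery/interior selection:
internal holes are filled (the nucleus belongs to the interior side), the
filled mask is eroded by a disc of the chosen depth (2 px default), and the
band between mask and erosion is the periphery. Manually drawn masks are
accepted through the same validated container. Pooled photons of each
region are fitted mono-exponentially, giving the paired $(\tau_P, \tau_I)$
per cell; paired two-sided t-tests summarize cohorts. Group comparisons
use one-way ANOVA plus Bonferroni correction applied to the *pre-declared*
relevant pairs only (the number of planned comparisons, not all possible
ones, scales the correction). Degenerate inputs are defined rather than
NaN: identical samples give $p = 1$, noise-free constant differences give
$p = 0$, flat responses regress with slope 0 and $R^2 = 0$. Acceptor
"expression level" is operationalized as mean acceptor-channel intensity
over the cell mask, in arbitrary units.

The cohort-level consistency check ties the two fitting routes together:
across cells spanning the FRET range, the OLS slope of mono-fit lifetime on
bi-exponential %FRET must reproduce the fixed-lifetime prediction
$-(\tau_{slow}-\tau_{fast})/100 = -0.0079$ ns per percentage point. The
acceptance suite asserts this within 15 %.

## File formats

* **PT3** — a minimal PicoHarp 300 T3-mode codec: 32-bit records packing a
  4-bit channel, 12-bit TCSPC time and 16-bit sync counter; channel 15
  carries overflow records (each advancing the sync counter by 65,536) and
  markers. The header is a documented 34-byte subset (identifier, version,
  resolution, sync rate, record count); vendor headers carry hundreds of
  bytes of hardware fields with no bearing on analysis. The writer inserts
  canonical overflow records, making write→read→write byte-identical.
* **Cubes and maps** — multi-page 32-bit-float TIFF plus a JSON sidecar
  with the acquisition metadata (`period_ns`, `bin_width_ns`,
  `pixel_size_um`, `frequency_mhz`, scale, dimensions). Values are stored
  scaled into $[0,1]$ by the recorded scale; integer counts round-trip
  exactly (counts are far below float32's $2^{24}$ integer limit), and
  undefined lifetime pixels are encoded as 0 on disk (lifetimes are
  strictly positive) and restored to `NA`.
* **Cell tables** — CSV with a fixed documented header
  (`cell, donor, condition, apparent_lifetime_ns, fret_percent,
  acceptor_intensity, tau_p_ns, tau_i_ns, n_photons`).

## Problem sizes used in the tests

The suite exercises the estimators at the study-scale settings (20 cells ×
750k photons for lifetime recovery; 10 replicates per FRET level; 40 cells
for the slope; 10 spatial cells for the region analysis) and scales down
where only the *property* matters: the paired-t null calibration uses 200
replicates of 6-cell cohorts at 80k photons per region, and pixel-wise
mapping tests run on 40–48-pixel cells with 128–256 time bins. These sizes
were chosen to give each assertion ~3σ statistical headroom under the
generator's noise model.

## Known limitations

* No free-lifetime multi-exponential fitting; the fixed-lifetime design is
  deliberate (see above) and per-pixel fitting is mono-exponential only.
* Phasor support is first-harmonic two-component; no multi-harmonic
  unmixing or phasor-space clustering.
* The PT3 codec targets PicoHarp T3 only (no PTU/HT3); line/frame image
  reconstruction from markers follows a documented convention flag rather
  than any vendor's.
* Statistical summaries treat cells as independent; donor-level random
  effects are simulated and recorded but not modeled (no mixed-effects
  fitting).
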