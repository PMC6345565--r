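---
title: "Modelling homobivalent scaffold binding on membrane sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling homobivalent scaffold binding on membrane sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzavidity)
```

## The binding problem

Scaffold proteins with two identical binding domains — the PICK1 dimer with
its two PDZ domains is the motivating case — bind pairs of identical
membrane-embedded target sites far more strongly than the intrinsic
single-domain affinity suggests. Two mechanisms compete once one domain has
bound: the remaining free domain can close intramolecularly onto the
neighbouring site (avidity), or a second ligand from solution can occupy
that site first. Which route wins depends on the bulk ligand concentration,
and the outcome changes both the apparent saturation behaviour and the shape
of dissociation time courses. This package provides the kinetic model of
that competition plus the surrounding assay-analysis machinery.

## The kinetic scheme

A target pair is tracked through four occupancy states: free (`U`), singly
bound (`G`, the pooled pair of mirror-image singly bound forms), bivalently
bound (`R`) and the two-ligand ternary complex (`B`). All steps are
reversible mass-action processes with intrinsic rate constants `k1`
(association, M⁻¹min⁻¹) and `k_off` (dissociation, min⁻¹). Closure of `G`
into `R` is first-order with the composite rate

$$k_2 = \frac{k_1 [L]}{f}, \qquad
  [L] = \frac{1}{N_A \tfrac{2}{3}\pi r^3},$$

where `[L]` is the effective concentration of the tethered second domain —
one molecule in a half-sphere of the inter-domain reach radius `r` — and `f`
is a dimensionless penalty for steric hindrance, restricted rotation and
entropic cost. For `r = 180 Å`, `[L]` is 136 µM; with `k1 = 1.85e5` and
`f = 185`, `k2 = 0.136 min⁻¹`. The bulk ligand is assumed in large excess:
its concentration is exactly constant during incubation and exactly zero
during washout, and released ligand never rebinds from the bulk. A
depletion mode is deliberately out of scope.

### Statistical factors

Pooling the two mirror-image singly bound species into one `G` compartment
requires path-multiplicity ("statistical") factors on four of the fluxes:

```
dU/dt = −s1·k1·aa·U + k_off·G
dG/dt =  s1·k1·aa·U − k_off·G − k2·G + s2·k_off·R − s3·k1·aa·G + s4·k_off·B
dR/dt =  k2·G − s2·k_off·R
dB/dt =  s3·k1·aa·G − s4·k_off·B
```

The factors are configurable (`rate_parameters(..., stat_factors = )`), and
the package ships `s = (2, 2, 2, 1)` as the default. This choice was made
once, by requiring the pooled scheme to reproduce the two published
benchmark behaviours of the full simulation — a half-maximal concentration
of about 50 nM for the 120-min saturation curve and a ternary/bivalent
crossover of order 100 nM — over the full grid of conventional
combinations; no textbook assignment (all ones; first-step factor 2 with
symmetric reverse factors) lands inside both benchmarks simultaneously,
which reflects genuine freedom in how the pooled compartment absorbs the
multiplicities of the underlying five-species scheme. With the default, the
simulated half-maximum falls at 47–50 nM (depending on grid density) and
the crossover at about 226 nM.

### Signal definition

The default readout counts bound ligand molecules per target pair,
`signal = G + R + 2B`, matching a fluorescence-per-receptor measurement in
which the ternary complex carries two labelled ligands. A complex-count
alternative (`G + R + B`) is selectable via `signal = "complex"`.

### Integration

Production simulations use the stiff-capable adaptive solver `deSolve::lsoda`
with `rtol = 1e-8`, `atol = 1e-12`; the rate constants span four orders of
magnitude, and at high bulk concentration the association fluxes are much
faster than `k_off`, so a fixed-step explicit method is wasteful. A
fixed-step explicit Euler integrator (`method = "euler"`, default step
0.001 min) is retained purely as an independent cross-check; the test suite
requires the two to agree to within 0.5 % of the peak signal on the
standard scenarios, and they in fact agree to about 1e-5. Target-pair
conservation (`U+G+R+B = 1` within 1e-8) and non-negativity (no excursion
below −1e-10) are asserted on every solver output rather than silently
repaired.

The monovalent reference (`simulate_monovalent()`) models a ligand with one
functional domain — e.g. a scaffold heterodimer with one inactivated binding
groove — as plain single-site kinetics (on-rate `k1·aa`, off-rate `k_off`,
no statistical factor), whose long-time occupancy is the Langmuir isotherm
with `Kd = k_off/k1 = 45.9 nM` for the stock parameters.

## Empirical curve fits

All empirical fits use unweighted nonlinear least squares
(Levenberg–Marquardt via `minpack.lm::nlsLM`, with a `port`-algorithm
fallback that is robust on noiseless, zero-residual inputs). Start values
are deterministic and documented: dose–response midpoints start at the
concentration whose mean signal is nearest half-range; decay rates start
from log-linear regression on the early and late thirds of the time range.
Replicates enter as individual points; independent experiments can be
rescaled to their fitted top with `normalize_experiments()` before pooling.

* **Saturation / competition** (`fit_dose_response()`, `fit_competition()`):
  four-parameter log-logistic
  `y = bottom + (top − bottom) / (1 + 10^((log10 EC50 − log10 c)·h))`,
  with the Hill slope pinned to 1 by default (single-site paradigm) and
  freed under `variable_slope = TRUE`. Experimental-style fits use the
  fixed slope; fits of simulated biphasic curves use the variable slope.
  EC50/IC50 are fitted on the log10 scale and reported with delta-method
  standard errors.
* **Association** (`fit_association()`): mono-exponential rise to plateau;
  the half-maximum binding time is `ln 2 / k_obs`.
* **Dissociation** (`fit_decay()`): one- or two-phase exponential with the
  plateau fixed at 0 by default, appropriate for washout data normalized to
  the washout start; an estimated plateau is available for one-phase fits.
  Two-phase fits are flagged degenerate when the rates come out within a
  factor of 2 of each other or either amplitude fraction collapses below
  1 % — thresholds chosen to catch re-fits of genuinely single-phase data.
* **Model comparison** (`compare_decay_models()`): the two-phase model is
  preferred only when its AICc (residual-variance form, error variance
  counted as a parameter) is lower by more than 2 and the fit is not
  degenerate. The threshold of 2 is the conventional "positive evidence"
  cut; a degenerate richer model is never preferred regardless of AICc.

## Fluorescence polarization

Polarization is `(IV − g·IH)/(IV + g·IH)`; units of the inputs cancel and
`fp_free`/`fp_bound` absorb any instrument scale (mP or raw), so the package
treats polarization units as opaque. The saturation model is the standard
single-site weighted average
`FP = FPf + (FPb − FPf)·Rt/(Kd + Rt)`, and the competition model
`FP = FPf + (FPb − FPf)·Rt/(Kd·(1 + x/Ki) + Rt)`, which reduces exactly to
the saturation model at `x = 0`. The total protein concentration is treated
as free protein: the tracer is at trace concentration (tens of nM against
micromolar Kd), so depletion is ignored, consistent with the model's form.
`fit_fp_competition()` requires the apparent Kd from a prior saturation fit
and holds it, and `Rt`, fixed.

## Membrane-sheet quantification

Per-sheet two-channel ROI statistics are reduced to the normalized binding
ratio ligand/receptor. The intensity correction is
`I_corr = (I_obs / L)·G(V) − I_back·G(V)`: division by the labeled fraction
`L` compensates invisible unlabeled protein, and `G(V) = (V2/V1)^(α·n)` is
the PMT gain correction between detector voltages. Both corrections are
isolated one-line functions, so the alternative reading of the labeling
correction (multiplication) is a one-line change; division was adopted
because unlabeled protein makes the raw intensity an undercount. The dye's
280-nm contribution in the degree-of-labeling computation is configurable
(`cf_280`, default 0). `α` and `n` are instrument constants supplied via
configuration; the package asserts no physical defaults for them. QC
discards sheets with saturated pixels or with observed intensity below the
sheet's own background plus 2 background standard deviations (the
`sigma_mult` is adjustable); the gain correction cancels in the ratio when
both channels share the same gain change, which the tests assert.

## Synthetic data and what the tests show

The generator module emulates the structure of each experiment with known
ground truth: sigmoidal saturation tables (stock truth Kd* = 47 nM,
Bmax = 100, 7 log-spaced concentrations from 1 nM to 1 µM, 3 replicates),
one-/two-phase decay traces (stock half-lives 431 min, and 21/373 min with
a 0.4 fast fraction, sampled every 30 min to 600 min), FP titrations
(Kd = 9 µM, Ki = 2.1 µM), ROI tables with planted pass/saturated/dim
sheets, and tables sampled from the mechanistic simulator itself. Noise is
Gaussian and proportional to signal by default — microscopy-derived ratio
data scatter multiplicatively — at 5 % for dose–response and washout
signals and 2 % for the normalized decay traces used in recovery checks; an
absolute-noise option exists. Every generator is bit-reproducible under a
seed and leaves the caller's RNG stream untouched.

Two consequences of these choices are worth stating plainly. First, on
noiseless simulated washout data an information criterion always prefers
the two-phase model, because even at low pre-incubation the small ternary
pool leaves a few-percent fast amplitude; the published qualitative
contrast — two-phase dissociation after 200 nM pre-incubation, one-phase
after 20 nM — emerges under realistic measurement noise, where a ~6 % fast
amplitude is indistinguishable from noise while a ~50 % one is not. The
model-selection checks therefore run on generator output at its default
noise level. Second, passing recovery tests show that the estimators are
unbiased at the stated noise under Gaussian assumptions; they do not show
robustness to the failure modes of real microscopy data (uneven
illumination, segmentation errors, non-Gaussian outliers), which the QC
filter only partially addresses.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to keep the full suite under a minute of compute: 12-point
concentration grids for simulated saturation fits, 21–41-point time
courses, 50–100 Monte-Carlo seeds for median-bias checks, and 100 random
parameter sets for conservation properties. Bisection for the species
crossover runs on log concentration to a relative tolerance of 1e-3.
Noiseless round-trip fits are required to recover generating parameters to
0.1 %; solver-vs-oracle agreement to 0.5 % of peak; conservation to 1e-8.

## Known limitations

* The pooled-`G` formulation cannot represent asymmetric kinetics between
  the two mirror-image singly bound species; the statistical factors absorb
  their multiplicities only in aggregate.
* No allosteric coupling between the two sites, no explicit
  membrane-anchoring step, and no bulk-ligand depletion are modelled; the
  penalty factor `f` implicitly lumps such effects.
* The mechanistic model is not fitted to experimental curves; it is a
  forward simulator compared to data qualitatively. Curve fitting is
  confined to the empirical models.
* Asymptotic (not bootstrap) standard errors; unweighted least squares
  throughout.
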