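---
title: "Inferring binding constants from fluorescence anisotropy assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring binding constants from fluorescence anisotropy assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabind)
```

## The measurement and the model

Fluorescence anisotropy reports the rotational mobility of a fluorophore:
a small labelled probe tumbles fast and shows low anisotropy `rf`; once
bound to a large protein it tumbles slowly and shows high anisotropy `rb`.
A titration of probe with protein therefore traces the probe's fractional
saturation, and a titration of a probe–protein mix with an unlabelled
competitor traces displacement. fabind turns such plate-reader tables into
dissociation constants.

The observation model is a two-state mixture. With the free-probe
intensity fixed at 1 arbitrary unit and the bound/free intensity ratio
`R = Ib/If`, the measured total intensity and anisotropy at probe
saturation $\nu_b$ are

$$I_t = (1-\nu_b) + R\,\nu_b, \qquad
  r = \frac{(1-\nu_b)\,r_f + R\,\nu_b\,r_b}{I_t}.$$

Many fluorescein conjugates brighten on binding (here `R = 3.1`), so the
anisotropy is *not* a linear interpolation between the endpoints: the
bound species is over-weighted. Inverting the mixture exactly gives

$$\nu_b = \frac{r - r_f}{(r - r_f) + R\,(r_b - r)},$$

which `add_saturation()` applies (method `"quantum_yield"`). The naive
linear inversion $(r-r_f)/(r_b-r_f)$ (method `"simple"`) is exact only
when `R = 1`; for `R != 1` it returns the *fluorescence* fraction bound,
a systematically biased estimate of the molar fraction (at `r = 0.121`
with the default probe it reports 0.46 where the true saturation is
0.21). Both quantities are returned so the bias is always visible.

## Exact equilibrium with ligand depletion

At the nanomolar concentrations these assays run at, bound ligand is a
large share of total ligand, so free concentrations must never be
approximated by totals. All binding is 1:1 with one site class. For the
probe alone, `solve_binary()` uses the numerically stable closed form of
the binding quadratic. With a competitor, conservation of sites, probe
and competitor combined with the two mass-action laws reduces to one
equation in the free-site concentration $x$:

$$T = x + \frac{P\,x}{K_{d,p} + x} + \frac{L\,x}{K_{d,l} + x},$$

whose left side is strictly increasing in $x$, vanishes at $x = 0$ and
exceeds $T$ at $x = T$. `solve_competition()` therefore brackets on
$[0, T]$ and bisects; a guaranteed bracket and a unique root were chosen
over speed (no spurious roots, no divergence). One hundred halvings put
the interval below one ulp of $T$, and every returned state carries its
conservation residual (hard error above 1e-8 nM; in practice residuals
are at rounding level, ~1e-13 nM). The test suite checks the solver
against an algorithmically independent damped fixed-point iteration on
1000 random systems.

Constants are dissociation constants in nM everywhere in the interface;
`glance()` and the CLI reports also emit the association constant
`Ka = 1/Kd` in M^-1 for comparison with literature values.

## Fitting

**Direct titration** (`fit_direct_kd()`): per replicate, each well's
anisotropy is inverted to $\nu_b$, the free-site concentration is
depletion-corrected as $x = T - \nu_b P$ (floored at 0), and the
single-site isotherm $\nu_b = x/(K_d + x)$ is least-squares fitted.

**Competition** (`fit_competition_kd()`): per replicate, the competitor
Kd is fitted by minimising squared residuals between measured anisotropy
and the anisotropy predicted by the exact competitive equilibrium pushed
through the forward observation model. Residuals are taken in anisotropy
space because the instrument noise is additive on `r`; inverting first
would warp the error distribution near the endpoints, where the
inversion's derivative blows up.

Both fits are one-parameter problems, so the optimiser is a bounded
golden-section search on $\log_{10} K_d \in [-2, 7]$ (nM) via
`stats::optimize` with tolerance 1e-9. The log parameterisation enforces
positivity and equalises conditioning across the five decades the panel
spans; a bounded derivative-free search needs no starting value and
cannot step outside the physical range. Estimates at the search boundary
are flagged unconverged.

Noise handling: anisotropies pushed outside `[rf, rb]` by noise keep
their algebraic (unclamped) saturation for fitting, with a clamped copy
and a per-well flag for reporting — silent clamping would bias estimates
near the endpoints, where half the noise distribution would otherwise be
rectified.

Degenerate inputs are reported, not guessed at: a flat direct series
(saturation range < 1e-3 or maximum < 0.02) returns a `no_binding` flag
with no Kd; a displacement series whose anisotropy drop at the highest
competitor concentration is below 0.005 returns a `no_displacement` flag
plus a *lower bound* on the Kd — the weakest affinity that would still
have produced a detectable (0.005) drop at that concentration. Fewer
than 4 distinct concentrations per replicate is an error.

**Replicates.** Fits are per replicate, aggregated as mean ± SEM with
the sample SD (`ddof = 1`); SEM is reported only for n ≥ 2. Replicates
are not pooled into one global fit: the reporting convention mean ± SEM
over n independent experiments is only meaningful for independent
per-replicate estimates.

**Assay quality.** `zfactor()` computes
$Z = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ from positive (bound)
and negative (free) control wells, ≥ 3 wells each, sample SDs. Z is
invariant under positive affine rescaling, so mA and dimensionless
readings score identically.

## The synthetic generator

No raw plate data accompany the assay this package models, so the
generator is a first-class module: it emulates the study conditions and
closes the loop generator → solver → observation model → fit.

Defaults are the reference assay design: probe at 10 nM; direct
titrations over sites 0–400 nM (zero plus 12 log-spaced points);
competition at fixed 4 nM sites with 12 competitor concentrations
log-spaced from 0.1x to 1000x the competitor's Kd; endpoint parameters
rf = 0.016, rb = 0.245, R = 3.1; probe Kd 6.8 nM; three replicates.
Noise is additive Gaussian on anisotropy (default SD 0.001, the reported
free-endpoint scatter) and independent multiplicative Gaussian on
intensity (default relative SD 0.016, the reported bound-intensity
scatter 0.05/3.10), applied per well. Noise is placed on `r` and `It`
directly, not on polarised channel intensities, because only `r` and
`It` are observed quantities with reported uncertainties; channel-level
simulation would add structure nothing could verify. Seeds give byte-identical
output and leave the caller's RNG state untouched.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real plates: edge effects, temporal drift, gain
auto-adjustment, DMSO effects, probe photobleaching, heteroscedastic
noise, or any deviation from 1:1 single-site binding (multiple site
classes, cooperativity, slow equilibration). Parameter recovery here
validates the *inference machinery*, not the chemistry of any particular
plate.

## Numerical and design notes

* The observation-model identities are exact to 1e-12 across the full
  saturation range (round trip, R = 1 reduction), and noiseless
  generate-then-fit recovers the generating Kd to ~1e-8 relative across
  the whole reference panel — see `run_recovery_panel()`.
* On replicate-noise statistics: a mean ± 3·SEM interval built from
  n = 3 replicates is a ~90% interval (the relevant t distribution has
  2 degrees of freedom; P(|t| ≤ 3) ≈ 0.905, and 95% coverage would need
  ±4.30·SEM). Simulated coverage in the test suite matches this t-theory
  value, which is the expected behaviour of an unbiased estimator with
  honestly estimated SEMs at n = 3.
* Two reference calibrations of the same probe circulate in the bundled
  panel: Kd = 6.8 nM and Ka = 1.6e8 M^-1 (i.e. Kd = 6.25 nM), differing
  by ~10% (plausibly a mean-of-Ka versus mean-of-Kd aggregation across
  replicates). They are used only as independent generator settings and
  never cross-checked against each other.
* At the reference competition conditions (probe 10 nM, sites 4 nM,
  Kd 6.8 nM) three different "fraction bound" quantities coexist: probe
  saturation ≈ 0.21, site occupancy ≈ 0.54 and fluorescence fraction
  ≈ 0.46. fabind always means *probe saturation* by `nu_b`; the
  fluorescence fraction is reported alongside as
  `fluor_fraction_bound`.
* Problem sizes in the shipped suites: property grids of 500–1000
  points, 300–1000 random systems for solver cross-checks, and
  200 noisy simulations per panel compound at 3 replicates each —
  chosen to estimate coverage proportions to ~2% Monte-Carlo error.

## A worked run

```{r example, eval = FALSE}
probe <- reference_probe(kd_nM = 6.8)

# synthetic displacement plate for a 15 nM competitor, 3 replicates
plate <- simulate_displacement(probe, ligand_kd_nM = 15,
                               sigma_r = 0.002, seed = 42)
fit <- fit_competition_kd(plate)
fit
glance(fit)
ggplot2::autoplot(fit)

# the full noiseless end-to-end panel
run_recovery_panel()
```

## Limitations

Single site class, 1:1 stoichiometry, equilibrium only (no kinetics), a
two-state photophysical model (no pKa-dependent fluorescein behaviour),
and no vendor plate-format parsers — input is the package's annotated
CSV dialect (see `write_plate_csv()`).
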