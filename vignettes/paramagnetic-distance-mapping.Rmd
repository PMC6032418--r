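---
title: "Mapping substrate protons onto the heme iron by paramagnetic relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping substrate protons onto the heme iron by paramagnetic relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predist)
```

## The physical model

A ferric (Fe3+) cytochrome P450 is paramagnetic. A substrate proton that
spends part of its time near the heme iron relaxes faster than it would in
free solution, and the enhancement falls off as the sixth power of the
proton-iron distance. When the substrate exchanges rapidly between the
bound and free pools, the observed longitudinal relaxation rate is the
population-weighted average, so dilute enzyme is enough: the bound-state
enhancement leaks into the easily measured bulk signal.

Three measured quantities feed the distance:

1. **T1P**, the purely paramagnetic relaxation time. The ferrous-CO
   complex of the same enzyme is diamagnetic, so its rate serves as the
   complete diamagnetic reference:
   `1/T1P = 1/T1(ferric) - 1/T1(ferrous-CO)`.
2. **alpha_m**, the fraction of substrate molecules bound at any instant,
   `[P450] / (Ks + [S])`, with Ks the spectral binding constant from a
   type I difference titration.
3. **S(S+1)**, the effective electron spin factor. Ferric heme is a
   temperature- and ligand-dependent mixture of low spin (S = 1/2) and
   high spin (S = 5/2); the population-weighted factor is
   `8.75 f_HS + 0.75 f_LS`, with the fractions from Soret-band
   deconvolution.

With the correlation time `tau_c` of the electron-nuclear dipolar
interaction these combine into the sixth-root distance relationship

```
r = [9.78e16 * T1P * alpha_m * S(S+1) * tau_c]^(1/6)   (Angstroms)
```

The prefactor carries implicit units of A^6 s^-2, so every time enters in
seconds. For CYP1A2 the package uses `tau_c = 3.38e-10 s`. Because of the
sixth root, r is remarkably insensitive to error in every input: a 10%
error in any single factor moves the distance by only ~1.6%.

## Stage by stage

### Inversion-recovery T1 fits

`fit_inversion_recovery()` fits peak height versus recovery delay to the
three-parameter model `H(d2) = Hinf (1 - 2 B exp(-d2/T1))`. The
inversion-efficiency factor `B`, bounded to (0.4, 1.1], absorbs imperfect
180-degree pulses; the ideal two-parameter model is the special case
B = 1. We default to the three-parameter form because real pulse
calibration is never perfect and the extra parameter costs little with
the ten or more delays of a routine measurement. Starting values are
`Hinf = max(height)`, `B = 1`, and `T1 = t0/ln 2` from the sign-change
delay `t0` (median delay if the series never changes sign); on
non-convergence the fit restarts with the T1 start scaled by 0.3, 0.5, 2,
3 and 5 before raising an error.

```{r}
d <- seq(0, 15, length.out = 10)
h <- 100 * (1 - 2 * exp(-d / 1.54))
fit_inversion_recovery(d, h, proton_label = "-OCH2-")
```

### Spectral binding

`fit_binding_isotherm()` fits the one-site hyperbola
`dA = Bmax [S] / (Ks + [S])` by unweighted least squares (no weighting
scheme is part of the protocol; difference-absorbance noise is roughly
constant across a titration). Fits where the data never reach the fitted
Ks, or where Ks exceeds ten times the largest titrated concentration, are
flagged rather than rejected. Solvent dilution over a titration (2 uL
aliquots into 800 uL) is below ~2% cumulative volume and is ignored.
`classify_difference_spectrum()` labels a spectrum type I when the global
maximum falls in 385-400 nm and the minimum in 415-425 nm (the
characteristic water-displacement signature), type II for the reversed
430/400 nm pattern of nitrogen ligation, and indeterminate otherwise.

### Spin-state deconvolution

`fit_soret_bands()` decomposes a 320-500 nm absolute spectrum into three
Gaussians on the wavelength axis — the delta band near 360 nm, the
high-spin Soret band (center window 385-407 nm) and the low-spin Soret
band (412-424 nm) — plus an optional linear baseline (default on). Spin
fractions are area ratios of the two Soret bands only; the delta band is
a separate feature of heme absorbance, not a spin marker, so it is fitted
to keep it from contaminating the high-spin band but excluded from the
ratio.

Two deliberate choices deserve comment. First, bands are fitted in
wavelength rather than energy; band positions and widths for these
enzymes are reported in nm, and at the Soret band's ~10% fractional
bandwidth the Jacobian correction between the two parameterizations
shifts areas by far less than the fit uncertainty. Second, the band
*widths* are fixed by default (delta 18, high-spin 14, low-spin 12 nm
Gaussian SD) and only the amplitudes and centers are fitted. Overlapping
Gaussian areas are poorly identified jointly with their widths: at 1%
photometric noise the likelihood has a soft direction that trades
high-spin width against low-spin area, and simulation shows the
resulting scatter in f_HS is two to three times larger than with known
shapes. Band widths are stable properties of an enzyme's spectrum that a
laboratory establishes once (from ligand-free, substrate-saturated and
reference spectra), so the protocol treats them as inputs;
`fit_widths = TRUE` frees them within 4-40 nm for the cases where the
shapes themselves are in question.

```{r}
sp <- sim_soret_spectrum(f_high = 0.27, total_area = 100, noise_sd = 0)
fit <- fit_soret_bands(sp$wavelengths, sp$absorbance)
c(f_low = fit$f_low, f_high = fit$f_high, ss1 = spin_factor(fit))
```

### Distances and their errors

`run_study()` chains the stages per enzyme. Error propagation is
first-order and deliberately narrow: only the T1 fitting errors enter.
`var(1/T1P)` is the quadrature sum of the two rate variances (the two
states are measured in separate experiments, hence independent), and the
sixth root maps a relative T1P error onto one sixth the relative distance
error: `se(r) = (r/6) * se(T1P)/T1P`. Uncertainty in Ks, the spin
fractions and tau_c is not propagated — those are study-level constants
whose quoted errors are not per-proton, and the sixth root suppresses
their influence on r to the sub-percent level anyway.

The first-order approximation deserves a caveat that the package
surfaces rather than hides: when the ferric and ferrous-CO T1 values are
nearly equal, the *rate difference* 1/T1P is small and its relative error
large (it can approach or exceed 100% even with ~10% T1 errors). In that
regime the sampling distribution of r is strongly right-skewed and a
Monte-Carlo standard deviation exceeds the analytic one by tens of
percent; the analytic value then understates the width of the right
tail. For well-separated pairs the two agree within a few percent (see
the test suite's Monte-Carlo comparisons).

### Fast-exchange diagnostic

The distance model assumes exchange fast enough that the bound-state
relaxation averages into the bulk. `fast_exchange_check()` regresses
1/T1P on 1/T over at least three temperatures: in fast exchange the
paramagnetic rate rises with temperature-driven exchange, giving a
positive slope; the diagnostic requires slope > 0 and R^2 >= 0.95.

## The bundled case study

`cyp1a2_phenacetin_study()` ships the complete input set for phenacetin
bound to CYP1A2 wild type and the N312L, L382V and L382V/N312L mutants:
per-proton T1 pairs with standard errors, enzyme and substrate
concentrations, Ks values, phenacetin-bound spin fractions, and
tau_c = 3.38e-10 s.

```{r}
report <- run_study(cyp1a2_phenacetin_study())
compare_site_of_metabolism(report, "-OCH2-")$ranking
```

One input required a correction: the L382V enzyme concentration. The
recorded 0.0007 uM in the bundled configuration replaces an originally
reported 0.007 uM, which is inconsistent with every distance reported for
that enzyme (it would scale all four by 10^(1/6) = 1.468). The corrected
value is one thousandth of that enzyme's Ks — exactly the ratio the other
three studies share — and reproduces all four L382V distances. The
configuration records the correction in the study's `note` field so it
surfaces in reports rather than being silent.

A second numerical observation: the correlation time is used as
3.38e-10 *seconds*. Quoted with reciprocal-second units in places, only
the seconds reading is dimensionally coherent in the sixth-root
expression and reproduces the benchmark distances.

Of the twenty proton-enzyme distances in the bundled study, nineteen are
reproduced within 0.05 A of their reference values from the tabulated
2-decimal inputs. The exception is the N312L -COCH3 proton (computed
7.93 A vs 8.19 A): its T1 pair differs by only 0.06 s, so T1P ~ 41 s is
hypersensitive to the 2-decimal rounding of the stored T1 values — a
half-ulp (0.005 s) perturbation of the pair moves the distance to
8.16 A. The package reports what the stored inputs imply rather than
adjusting them.

## What the synthetic generators emulate — and what they do not

The four `sim_*` generators produce mono-exponential recovery curves,
hyperbolic isotherms, three-Gaussian Soret mixtures, and whole studies
inverted from target distances (T1P from r via the sixth-power
relationship, a diamagnetic T1 drawn uniformly from 1-5 s to bracket the
measured range, the ferric T1 from the rate sum). Noise is additive
i.i.d. Gaussian in every modality (relative, on T1 values, in the study
generator), which matches the fitting assumptions but deliberately omits
features of real data: baseline drift and scatter in spectra,
temperature instability, radiation damping and incomplete relaxation in
NMR, exchange-regime violations, and correlated wavelength noise.
Passing the round-trip suites therefore demonstrates that the estimators
are unbiased and correctly calibrated under their own model, not that
real spectra are this well behaved.

Default study conditions mirror the bundled case: [P450] ~ 0.004-0.017
uM against substrate at 10x Ks (alpha_m ~ 1e-4), spin fractions 0.06-0.27
high spin, 1% measurement noise where a noisy default is wanted.

## Problem sizes and numerical choices

All fits run through bounded Levenberg-Marquardt
(`minpack.lm::nlsLM`, up to 200-400 iterations). Replicate suites in the
tests use 500 inversion-recovery fits (coverage of the +/-2 SE interval),
200 isotherm refits per Ks in {0.7, 3.5, 10.2, 17.1} uM, 100
deconvolutions per composition in {6, 14, 21, 27}% high spin, and 200
study round trips; Monte-Carlo error comparisons use 10,000 draws. Ties
and degenerate inputs fail loudly: fewer than 4 distinct delays, fewer
than 5 titration points, fewer than 50 spectral points, non-ascending
axes, non-positive concentrations, and T1 pairs with no paramagnetic
effect are all input errors, while per-proton failures inside
`run_study()` are collected as warnings so one bad resonance does not
abort an enzyme.

## Limitations

- The diamagnetic-reference subtraction assumes the ferrous-CO complex
  reproduces every non-paramagnetic relaxation pathway of the ferric
  sample.
- tau_c is taken as a constant for the enzyme; multi-field measurements
  to determine it are out of scope.
- Outer-sphere (non-bound) paramagnetic relaxation is not modelled.
- The distance is a population- and conformation-averaged quantity; it
  constrains docking but does not by itself define a pose.
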