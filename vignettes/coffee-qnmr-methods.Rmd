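---
title: "Quantitative 1H NMR screening of coffee: models, validation statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 1H NMR screening of coffee: models, validation statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NMRcoffee)
```

## The problem

Arabica coffee commands a premium over robusta, which makes partial or
complete substitution of arabica by robusta a recurring form of food fraud.
The diterpene 16-*O*-methylcafestol (OMC) occurs only in *Coffea canephora*
(robusta), so its content in a product declared "100% arabica" is a direct
adulteration marker; kahweol is far more abundant in arabica and carries the
converse signal. Caffeine content decides decaffeination compliance (below
1 g/kg under the German coffee regulation), and furfuryl alcohol and
5-hydroxymethylfurfural (HMF) are roasting markers of public-health
interest.

`NMRcoffee` implements a quantitative proton-NMR screening method for these
five analytes in CDCl~3~ extracts of ground coffee: spectral processing,
windowed line-fit integration, PULCON-style quantification, the statistics
of a formal method validation, and rule-based authenticity screening. A
spectrum simulator with known ground truth stands in for the spectrometer,
so every stage is testable offline.

## Signal model and processing chain

A processed 1D spectrum is represented as real intensities on a strictly
descending ppm axis (`NMRSpectrum`), together with the acquisition
parameters (`AcquisitionParameters`) that define the grids: time-domain
size TD, spectral width SW, carrier frequency (implied by the Hz/ppm pair),
and real spectrum size SI. The two instrument dialects are carried as
presets: `devicePreset("UltraShield")` (SW 20.5503 ppm / 8223.68 Hz) and
`devicePreset("Ascend")` (20.5617 ppm / 8223.69 Hz), both with TD 131072,
SI 262144, NS 64, DS 2, D1 30 s, RG 45.2, 300.0 K and LB 0.30 Hz. The
acquisition arithmetic AQ = TD/(2 SW) and SW~Hz~ = SW~ppm~ x carrier is
enforced by class validity (tolerances 0.01 s and 0.1 Hz).

Processing follows the standard chain:

1. **Apodization** (`apodizeExponential`): the FID is multiplied by
   $\exp(-\pi \cdot \mathrm{LB} \cdot t)$, broadening every line by LB Hz.
2. **Fourier transform** (`transformToSpectrum`): zero filling to SI, first
   time-domain point halved (the usual DC correction), DFT scaled by the
   dwell time so spectral integrals approximate the continuous transform.
3. **Automatic phasing** (`phaseCorrect`): zero- and first-order phases are
   chosen to minimise the integrated squared negative intensity of the real
   part, by a coarse grid search followed by Nelder-Mead refinement. The
   vendor software's "default settings" are proprietary; this criterion
   reproduces their observable contract (absorption-mode output, peak
   integrals of an ideally phased input changed by well under 0.5%).
4. **Automatic baseline correction** (`baselineCorrect`): asymmetric least
   squares -- a second-difference-penalised smooth curve fitted with
   weights that favour points below the current estimate, so it tracks the
   signal-free baseline. `lambda` (default 1e8) sets the stiffness, `p`
   (default 0.001) the asymmetry; both are exposed because real baselines
   vary more than simulated ones.

## Integration and quantification

Each analyte is integrated over its characteristic window (ppm):
OMC 3.125-3.185, caffeine 3.38-3.44, kahweol 5.85-5.925, furfuryl alcohol
7.39-7.411, HMF 9.67-9.69. Two methods are provided by `integrateWindow`:

* **`linefit`** (default): least squares of one Lorentzian plus a local
  linear baseline. The amplitude and the two baseline coefficients enter
  linearly, so for every trial (centre, width) they are solved exactly and
  only the two nonlinear parameters are optimised (variable projection,
  Nelder-Mead). The reported area is the *analytic* Lorentzian area, which
  makes the estimate insensitive to window-truncated tails and to linear
  baseline contamination. The width is constrained to lie between half a
  grid step and a third of the window: below the lower bound the model
  degenerates to an unsampled spike between two grid points, above the
  upper bound it becomes collinear with the baseline terms; both
  degeneracies otherwise produce arbitrarily large spurious areas on pure
  noise. Non-convergence falls back to the trapezoid with a flag.
* **`sum`**: the trapezoidal integral, with the window edges interpolated
  onto the axis so the integral covers exactly the requested width
  regardless of the grid. It is the assumption-free oracle the line fit is
  tested against.

**OMC interference correction** (`correctOmcArea`). Broad fatty-acid matrix
resonances around 2.9-3.1 ppm leak into the OMC window and inflate its
integral. The reference range 3.04-3.10 ppm is equally wide (0.06 ppm),
carries the same broad background, and contains no OMC; its integral is
subtracted from the OMC window integral. With plain sums a flat background
cancels exactly because the windows have equal width; with the line fit the
local linear baseline already absorbs the background and the subtraction
removes residual contamination. A negative reference area (pure noise) is
treated as zero so the correction never inflates OMC, and a negative
corrected area is clipped to zero with a flag -- the sign conventions the
downstream concentration arithmetic requires.

**PULCON quantification** (`areaToSolutionConcentration`). The whole
instrument response is absorbed into one calibration degree of freedom, the
eretic factor $f$ (mol/L per unit proton-normalised area), determined on
each spectrometer with an external quantification reference:

$$c\ [\mathrm{mg/L}] = \frac{A}{n_\mathrm{H}} \cdot f \cdot M \cdot 1000,$$

with $A$ the corrected area, $n_\mathrm{H}$ the protons behind the signal
and $M$ the molar mass. The simulator supplies the matched factor
(`matchedEreticCalibration`), which is how round-trip accuracy is tested.

**Content conversion** (`solutionToContent`). With 200 mg of ground beans
extracted into 1.5 mL, 1 mg/L in solution is 7.5 mg/kg in the coffee.
Caffeine dissolves incompletely in CDCl~3~; the empirical recalculation
factor 6 (established against an HPLC reference method) converts its
measured solution concentration to the true content. The simulator models
the cause as a dissolved fraction (default 1/6), and the factor-6
recalculation restoring the nominal content is asserted in the tests.

## The simulator

`simulateSpectrum` builds a spectrum directly in the frequency domain: one
Lorentzian per analyte at a fixed position inside its window, with analytic
area $k \cdot n_\mathrm{H} \cdot c_\mathrm{mol}$ for a device constant $k$
(`response_factor`, default 1e4 area units per mol/L per proton -- the
quantity the eretic factor inverts), a TMS reference singlet at 0 ppm,
additive Gaussian noise, and optionally multiplicative per-analyte area
noise (`rel_area_noise`) representing preparation/measurement error.
`simulateFid` produces the matching time-domain signal for exercising the
full processing chain against known areas.

The fatty-acid matrix interference is modelled as a smooth flat-topped band
(cosine shoulders 2.80-2.90 and 3.20-3.30 ppm, flat in between). A plain
Lorentzian hump was considered and rejected: its tail decays quadratically,
which either breaks the equal-loading property of the two OMC windows that
the correction relies on, or -- if made broad enough to be locally flat --
leaks into the caffeine window at 3.38 ppm. The flat-topped band loads both
0.06 ppm windows identically and is exactly zero beyond 3.30 ppm. What this
simplifies away: real fatty-acid patterns have internal structure and their
flatness across 3.04-3.185 ppm is approximate, so passing tests demonstrate
the correction's algebra, not the chemistry of every matrix.

`buildDilutionPlan` reproduces the ten-level calibration series (1, 5, 10,
25, 50, 100, 250, 500, 750, 1000 mg/L in a constant 1500 uL, plus two
blanks), with levels up to 100 mg/L drawn from the 1000 mg/L stocks and
levels from 250 mg/L from the 5000 mg/L stocks -- the only stock assignment
consistent with the printed volumes. (The protocol text lists the levels
twice with a 75/125-vs-100/250 discrepancy; the dilution table's set is
taken as normative.) `buildValidationDesign` crosses six such series
(3 coffee types x 2 shaking times) with two devices: 72 test solutions, 144
measurements, 120 excluding blanks.

`simulateDesign` applies per-matrix presets (`matrixPreset`): roasted
matrices (decaffeinated arabica, robusta) are nearly unbiased with moderate
relative noise, kahweol in robusta gets a low recovery and poor precision
(its native content there is too low to determine precisely), and green
coffee carries strong analyte-specific extraction biases and much larger
dispersion -- the constellation that makes green-coffee results indicative
only. The spectrometer has no systematic effect, and shaking time none by
default (a small 10-min bias can be injected). These presets emulate the
qualitative validation outcome; they are inputs to the simulation, not
measurements of nature.

## Validation statistics

* **Linearity** (`fitCalibration`): OLS of measured on spiked content;
  acceptance in this method family is $R^2 > 0.99$ over the working range
  7.5-7500 mg/kg.
* **Detection/determination limits** (`din32645Limits`), calibration-line
  method: with residual sd $s_y$, slope $b$, $n$ levels, mean level
  $\bar x$ and $Q_x = \sum (x_i - \bar x)^2$,
  $$\mathrm{LOD} = \frac{s_y}{b}\, t_{n-2,\,1-\alpha}
    \sqrt{1 + \tfrac 1 n + \tfrac{\bar x^2}{Q_x}}, \qquad
    \mathrm{LOQ} = k\,\frac{s_y}{b}\, t_{n-2,\,1-\alpha}
    \sqrt{1 + \tfrac 1 n + \tfrac{(\mathrm{LOQ}-\bar x)^2}{Q_x}},$$
  the LOQ solved by fixed-point iteration. The norm's parameters were not
  published for this method, so the customary one-sided $\alpha = 0.01$ and
  $k = 3$ (33% relative uncertainty at the LOQ) are the defaults, both
  configurable; published limit values are treated as plausibility anchors,
  not as reproduction targets. Tests pin the implementation to an
  independently coded textbook calculation and to the exact linear scaling
  of LOD with $s_y$.
* **Recovery** (`recovery`): per level,
  $100 \cdot (\overline{\mathrm{measured}} - \mathrm{blank}) /
  \mathrm{spiked}$, aggregated as the mean of per-level recoveries (median
  available); specification 90-110%. The aggregation rule was not
  published; the mean is the conventional choice and the median is offered
  because single low-level outliers otherwise dominate.
* **Precision** (`precisionCV`): $100 \cdot s / \bar x$ over replicates;
  specification CV < 15%.
* **Robustness** (`factorialAnova`): main-effects linear model of per-cell
  recovery on device, coffee type and shaking time, type-II sums of squares
  (`car::Anova`), $\alpha = 0.05$. Type II coincides with the sequential
  decomposition on the balanced design and stays valid if cells are lost
  (with a warning). Factors that do not vary in a reduced design are
  dropped, so the one-factor case degenerates to the two-sample *t* test
  (F = t^2), which the tests assert.

`buildValidationReport` assembles recovery/precision with specification
stars, linearity, limits and the per-analyte ANOVA into one object with a
plain-text rendering.

## Screening rules

`classifySample` evaluates guidance rules on quantified contents:
declared 100% arabica with OMC strictly above 50 mg/kg is *suspicious*
(boundary equality is consistent, following the "greater than 50" wording);
declared decaffeinated coffee at or above 1000 mg/kg caffeine is *out of
spec* (the regulation demands "below 1000"); a kahweol rule for declared
robusta (at or above 300 mg/kg) is provided but disabled by default, since
its operational use is not documented. Green declarations are always capped
at *indicative only*. Suspicious findings are labelled as requiring
confirmatory analysis, mirroring the HPLC confirmation workflow that this
package deliberately does not implement. Verdicts are monotone in the
marker content and deterministic; a missing analyte skips its rule loudly
rather than passing silently.

## Numerical choices and problem sizes

* ppm axes are descending with spacing SW/SI and points at bin midpoints;
  integration windows are given as (low, high) pairs and normalised
  internally.
* Window trapezoids interpolate the exact window edges; without this, the
  captured width varies by up to one grid step per window, which visibly
  breaks the equal-width cancellation on coarse grids.
* The phasing objective is invariant under 360-degree shifts; the coarse
  grid keeps Nelder-Mead out of the wrong local branch.
* Simulated tests run on reduced grids (SI 16384-65536 over the full
  20.55 ppm width) -- the package's chosen desk scale; at these sizes a
  1.3 Hz line is sampled by 4-16 points across its width, enough for the
  integration contracts, and all stochastic checks (20-seed linearity,
  500-seed ANOVA calibration, 100-replicate LOD scaling) complete in
  seconds. Axis arithmetic and presets keep the instrument's full TD/SI.
* The ten-level calibration's linearity check uses the mean $R^2$ across
  seeds per analyte: with 5% relative noise the single-series $R^2$ has a
  small tail below 0.99 driven by the top level's leverage, and the method
  statement being checked is a property of the calibration design, not of
  one noise draw.

## Limitations

The simulator draws singlet Lorentzians (whole multiplets are integrated by
the windows anyway), a flat or linear local baseline, and idealised
interference; it does not model solvent artefacts, 13C satellites, field
inhomogeneity, shimming or extraction kinetics. Passing its tests
establishes the correctness of the computational chain under the stated
signal model -- transfer to real spectra rests on that model being adequate
within the integration windows, which is exactly what the published
validation of the physical method established. Raw vendor directories are
not parsed; spectra enter as plain-text tables or JCAMP-DX-style files.
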