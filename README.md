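# NMRcoffee

Quantitative ¹H NMR screening of coffee for quality and authenticity.

Roasted coffee declared "100% arabica" is routinely adulterated with
cheaper robusta. The diterpene 16-*O*-methylcafestol (OMC) occurs only in
robusta, so quantifying it — together with caffeine (decaffeination
compliance), kahweol (arabica character), furfuryl alcohol and
5-hydroxymethylfurfural (roasting markers) — from a single 1D proton NMR
spectrum of a CDCl₃ extract turns one measurement into a complete
quality-and-authenticity screen. This package implements that method for
analysts and method developers: spectral processing, line-fit integration,
PULCON quantification, full method-validation statistics, and rule-based
screening, plus a spectrum simulator with known ground truth that stands in
for the spectrometer so the whole pipeline runs and is tested offline.

## The method in brief

* **Processing**: exponential apodization (LB 0.30 Hz), zero-filled FFT,
  automatic phasing (minimum negative intensity) and asymmetric-least-squares
  baseline correction.
* **Integration**: per-analyte ppm windows (OMC 3.125–3.185, caffeine
  3.38–3.44, kahweol 5.85–5.925, furfuryl alcohol 7.39–7.411, HMF
  9.67–9.69); areas from a Lorentzian-plus-linear-baseline least-squares
  fit, with the plain trapezoid as the cross-checking oracle. Fatty-acid
  matrix interference in the OMC window is removed by subtracting the
  equally wide, equally affected reference range 3.04–3.10 ppm.
* **Quantification** (PULCON): with eretic factor *f* (mol/L per unit
  proton-normalised area), molar mass *M* and proton count *n*<sub>H</sub>,

  *c* [mg/L] = (*A*/*n*<sub>H</sub>) · *f* · *M* · 1000,

  converted to coffee content by 7.5 (mg/kg per mg/L; 200 mg beans in
  1.5 mL), with caffeine's empirical recalculation factor 6 compensating
  its restricted solubility in CDCl₃.
* **Validation**: DIN 32645 calibration-line detection/determination
  limits, linearity (*R*² > 0.99), recovery (spec 90–110%), precision
  (CV < 15%), and a 3-factor robustness ANOVA (device × coffee type ×
  shaking time) over the factorial design of 6 calibration series × 2
  spectrometers (72 test solutions, 144 measurements).
* **Screening**: declared arabica with OMC > 50 mg/kg → suspicious;
  declared decaf with caffeine ≥ 1000 mg/kg → out of spec; green coffee →
  indicative only.

## Worked example

Simulate a contaminated "arabica" extract, quantify it against the
simulator's matched eretic calibration, and screen it:

```r
library(NMRcoffee)

st  <- simulationSettings(noise_sd = 1, rel_area_noise = 0.02, seed = 11)
p   <- devicePreset("UltraShield", si = 65536)
sim <- simulateSpectrum(
  c(omc = 30, caffeine = 500, kahweol = 150, furfuryl_alcohol = 40, hmf = 15),
  settings = st, params = p)

cal <- matchedEreticCalibration(st)
q   <- quantifySample(sim$spectrum, cal = cal)
q[, c("analyte", "corrected_area", "concentration_mg_L", "content_mg_kg")]
#>            analyte corrected_area concentration_mg_L content_mg_kg
#> 1              omc          2.692              29.66         222.4
#> 2         caffeine         12.881              83.38        3752.0
#> 3          kahweol          4.623             145.35        1090.2
#> 4 furfuryl_alcohol          3.973              38.97         292.3
#> 5              hmf          1.217              15.35         115.1

classifySample(setNames(q$content_mg_kg, q$analyte), "arabica_100", "lot-0421")
#> Sample 'lot-0421' (declared arabica_100): SUSPICIOUS
#>   triggered: omc_arabica
#>   - omc_arabica: omc 222.4 mg/kg vs guidance 50 -- requires confirmatory analysis
```

Reading the numbers: 30 mg/L of OMC in solution is 29.66 mg/L measured
(the 2% simulated measurement noise), i.e. 222.4 mg/kg in the coffee —
far above the 50 mg/kg guidance for declared arabica, so the sample is
flagged for confirmatory analysis. Caffeine was simulated at 500 mg/L
nominal: only a sixth dissolves, the factor-6 recalculation restores the
content scale (≈ 500 × 7.5 = 3750 mg/kg). A full validation run is
available through `simulateDesign()` → `quantifyDesign()` →
`buildValidationReport()`; see the methods vignette
(`vignettes/coffee-qnmr-methods.Rmd`) for the models, parameter choices
and limitations.

A thin command-line wrapper with `simulate`, `quantify`, `screen` and
`validate` subcommands lives at `inst/scripts/nmr-coffee-screener.R`.

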