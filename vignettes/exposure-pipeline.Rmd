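---
title: "From GC–MS response to dietary risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GC–MS response to dietary risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmexposure)
```

This vignette is the package's own account of the model it implements, the
choices behind its defaults, and what its tests can and cannot demonstrate.

## Measurement model

All instrument observations are **response ratios**: the area of an
analyte's quantification ion in selected-ion-monitoring mode divided by the
area of the deuterated internal-standard ion (*m/z* 153). Normalising to an
internal standard removes injection-to-injection instrument variability but
not matrix effects, which motivates the standard-addition design below.

For the solvent (methanol) calibration the model is linear over the working
range,

$$y = a\,x + b,$$

with $x$ in µg/mL and $a, b$ fitted by unweighted ordinary least squares
over all replicate injections (`fit_calibration()`). No $1/x$ weighting is
applied: the package models simple linear regression as commonly practised
for narrow-range GC–MS calibration, and weighted or robust variants are
deliberately out of scope.

For a food extract the response at spike level $s$ (µg/g) is modelled as
proportional to the total amount of analyte recovered:

$$y = a\,R\,\frac{C + C_\mathrm{blank} + s}{f},$$

where $R$ is the recovery fraction, $C$ the native concentration,
$C_\mathrm{blank}$ additive batch contamination, and $f$ the extract factor
(mL of final extract per g of sample; 1 under the 1 g → 1 mL protocol).
Note the matrix line carries **no solvent intercept**: the solvent
calibration's small non-zero intercept is an artifact of the calibration fit
(adsorption, carryover at the instrument), not a property of the extracted
food, and including it would bias the x-intercept estimator away from the
truth for every recovery $R \neq 1$. The standard-addition estimate

$$\hat{C} = \frac{\text{intercept}}{\text{slope}}$$

is then invariant to $R$ (both coefficients scale by $aR/f$), which is the
whole point of the design. This invariance is exercised directly in the test
suite by scaling whole series by arbitrary $k > 0$ and by running noiseless
bundles at recoveries spanning 0.72–1.18, the range observed in validation.

## Order of operations and censoring

The pipeline order is fixed: **quantify → blank-subtract → censor**. Blanks
are subtracted from measured concentrations (floored at zero), and only the
blank-corrected value is compared with the limits. The alternative —
censoring before subtraction — would let blank contamination push a truly
absent analyte above the LOQ.

Censoring follows the GEMS/Food-EURO substitution convention:

* $C \ge \mathrm{LOQ}$: reported as measured (`quantified`); the boundary
  counts as quantified because "between LOD and LOQ" excludes its upper
  endpoint.
* $\mathrm{LOD} \le C < \mathrm{LOQ}$: reported as $\mathrm{LOQ}/2$
  (`below_loq`).
* $C < \mathrm{LOD}$: reported as 0 under the default lower-bound policy;
  the middle-bound alternative $\mathrm{LOD}/2$ is available via
  `below_lod = "half_lod"`. Only the LOD–LOQ case is prescribed by the
  convention's common usage here; the below-LOD default is the conservative
  lower bound, and both bounds are one switch apart for sensitivity
  analyses.

Censoring is idempotent — re-censoring a reported value changes nothing —
**provided** $\mathrm{LOQ} \ge 2\,\mathrm{LOD}$, so that the substitute
$\mathrm{LOQ}/2$ does not itself fall below the LOD. All eight bundled
analytes satisfy this (their LOQ/LOD ratios are 2 or 2.5), and the
property-based tests draw random limits in that regime. For pathological
limit pairs with $\mathrm{LOQ} < 2\,\mathrm{LOD}$ the substituted value
would be re-classified `below_lod` on a second pass; the package does not
special-case this because such limits do not arise from the S/N definitions
below.

The LOQ used to censor food results is the solvent LOQ converted to sample
units through the extract factor (at $f = 1$, 0.025 µg/mL ↔ 0.025 µg/g); no
matrix-matched LOQ is modelled.

## Sensitivity limits from signal-to-noise

`estimate_lod_loq()` reads a dilution series and returns the lowest tested
concentration whose signal-to-noise is **strictly** above the threshold:
above 10 on the quantification ion for the LOQ, above 3 on the qualifier
ion for the LOD. The source description of which ion carries which threshold
is ambiguous ("respectively" over a two-part sentence); the package fixes
the reading that pairs the stricter threshold with the quantification ion —
the ion actually used for quantification — and both thresholds are
arguments, so the opposite pairing is one call away. "Higher than" is
implemented as a strict inequality; a series that never crosses a threshold
yields an `NA` limit flagged `*_reached = FALSE` rather than an error, since
a non-reached LOQ is an ordinary screening outcome.

## Exposure arithmetic

Exposure is deterministic: $E = C_\mathrm{pool} \times \text{intake}$, with
the pool concentration treated as fixed and the mean or P95 consumption
statistic supplying the variability. No probabilistic (Monte-Carlo)
convolution is attempted; the P95 exposure is the P95 intake times the same
concentration.

The bundled consumption figures (1–2 years: 1.671, P95 8.508; 3–9 years:
0.9806, P95 4.265; 10–17 years: 0.3705, P95 1.932) are treated as **g per
kg body weight per day**, although their source labels them g/day: every
published exposure in the study these figures accompany equals
concentration × figure with no further body-weight division, so the per-kg
reading is the only arithmetically consistent one. The package flags rather
than resolves this labelling inconsistency: an `absolute_with_bw` mode is
provided for genuinely absolute intakes, which divides by a per-group body
weight first.

Reported values are rounded half-up to 3 significant figures — matching the
precision of the tables the fixtures transcribe — in a dedicated `reported`
column; the unrounded `value` column is always retained and all internal
computation is unrounded. `signif_half_up()` exists because base R's
`signif()` rounds half to even.

## Risk characterisation

* **Hazard quotient**: $HQ = E/\mathrm{TDI}$, with TDIs of 500 (DEP), 10
  (DBP) and 50 (DEHP) µg/kg bw/day; exceedance is strict ($HQ > 1$).
  Analytes without a TDI yield a not-assessable row, never an error.
* **Group-TDI**: the cumulative reproductive-toxicity total
  $\sum_i p_i E_i$ over DEHP, DBP, DiNP and BBP in DEHP equivalents
  (potencies $p_i$ default to 1) against 50 µg/kg bw/day.
* **TTC screen**: per-person exposure $E \times bw$ against the Cramer
  class thresholds 1800/540/90 µg/person/day (classes I/II/III), strict
  exceedance. Body weights are **not** study values — none are published
  with the consumption figures — so the screen requires a user-supplied
  table; the shipped `body_weights_example.csv` (12/24/50 kg) is
  illustrative only.

The screening-inventory triage reads the positive-list token of each
identified compound: a number is a specific migration limit in mg/kg; `+`
is the generic 60 mg/kg group restriction; `NI`/`NL` mean not included in
the positive list. The `ND` token is glossed "not detected" in the source
table's footnote, but it appears in the SML column of the four diisocyanates
— substances listed with a non-detectable-migration restriction — and the
published total of 20 regulated compounds out of 65 is reached only under
that reading. The package therefore counts `ND` as regulated
(`regulated_non_detectable`) and surfaces the status explicitly in its
output so the interpretation is auditable.

## The synthetic study

`generate_study()` emits a complete measurement bundle — solvent
calibrations, standard-addition series per analyte × pool, matching
procedural blanks, and a `truth.json` with every generating parameter. Its
defaults are the study conditions: the eight analytes with their fitted
solvent sensitivities; true pool concentrations equal to the bundled
concentration table, with the censored DNOP pools assigned 0.015 µg/g
(inside its 0.01–0.025 LOD–LOQ band, so a faithful pipeline re-censors
them); the observed per-pool recoveries (0.72–1.18); zero blank
contamination; 5% response CV (consistent with the validated repeatability
bound RSDr < 10% at n = 8); triplicate calibration injections; duplicate
unspiked-pool analyses; the {0, 0.05, 0.1, 0.25, 0.5} µg/g spike design.
Within-pool replicate variability is not reported numerically anywhere, so
the CV default is an assumption, not a calibrated value.

Noise is multiplicative mean-zero Gaussian on the response ratio with
constant CV across levels — the form that matches RSD-style precision
reporting. Blank contamination is additive in concentration and shared
between sample and blank within a batch, so subtraction removes it in
expectation. Sub-stream seeds derive deterministically from (study seed,
analyte index, pool index), making any slice of a bundle reproducible on
its own.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic peak shape and integration,
retention-time drift, carryover, heteroscedastic calibration noise,
saturation at the top of the range, and co-elution interferences. Tests on
synthetic bundles demonstrate the *estimators* are correct under the stated
model, not that the model captures every instrument pathology.

## Numerical choices and degenerate inputs

* OLS is delegated to `stats::lm`; the test suite cross-checks coefficients
  against a closed-form normal-equations oracle at 1e-10 relative
  tolerance. $R^2$ is computed directly as $1 - SS_\mathrm{res}/SS_\mathrm{tot}$
  (clamped to [0, 1]; defined as 1 for an exact fit to a flat response) so
  that noiseless series do not trip the "perfect fit" warning path.
* Degenerate designs (a single distinct x value) raise a domain error; a
  fitted standard-addition slope ≤ 0 raises a non-quantifiable error; a
  negative fitted intercept (native signal below baseline) reports 0 with a
  warning rather than a negative concentration. Warnings never abort a
  pipeline run.
* A spike design must contain the unspiked pool (level 0); the duplicate
  unspiked analyses enter the fit as replicate points rather than being
  pre-averaged, which is equivalent for the OLS estimate and keeps both
  raw values in the output tables.

## Problem sizes used by the tests

The stochastic checks run at sizes chosen to make Monte-Carlo error small
relative to the margins being asserted while keeping the whole suite in a
few seconds: 200 seeded replicates for the concentration-recovery error
(median relative error < 10% at 5% CV for truths ≥ 2 × LOQ) and for the
repeatability check (RSDr < 10% at n = 8 in ≥ 95% of runs), 150 replicates
per arm of the RMSE-vs-replication comparison, 1000 replicates for the
noise-CV calibration check, and 20–50 random cases per property-style
invariant.

## Known limitations

Fieller-style confidence intervals on the x-intercept are not computed;
blank modelling is single-point, not stochastic; exposure is deterministic
(no usual-intake or probabilistic model); the Cramer classes are input
data, not derived from structure; and migration-compliance testing against
the specific migration limits is out of scope — SMLs are carried as
metadata and used only for positive-list triage.
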