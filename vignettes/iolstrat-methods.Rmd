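---
title: "Methods: vergence formulas, lens-constant zeroization and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vergence formulas, lens-constant zeroization and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolstrat)
```

## The optical model

All four formulas in this package — SRK/T, Holladay 1, Hoffer Q and
Haigis — are thin-lens vergence formulas. They share one physical skeleton
and differ only in how they locate the implant. For an eye of optical
axial length $L$ (meters), corneal power $D_c$ (diopters), aqueous index
$n = 1.336$ and an IOL of power $P$ at effective lens position $C$ (the
ELP, measured from the corneal vertex), the corneal-plane refractive error
is

$$R_c = \frac{n}{C + \dfrac{n}{\dfrac{n}{L - C} - P}} - D_c,$$

transposed to the spectacle plane at vertex distance $v$ (12 mm by
default) as $R_s = R_c / (1 + v R_c)$. `vergence_refraction()` implements
exactly this chain; `emmetropic_power()` and `power_for_target()` are its
closed-form inversions. The chain is continuous and strictly decreasing in
$P$, and strictly increasing in $C$: assuming the lens sits more
posteriorly makes the predicted outcome more hyperopic. Both monotonicity
properties are load-bearing — the first for IOL power selection, the
second for constant optimization — and both are property-tested on random
valid eyes.

Each formula's ELP model follows its original publication (including
published errata), with every physical constant held in configuration
rather than inlined:

* **SRK/T** — A-constant mapped linearly to an ACD constant
  ($0.62467A - 68.747$) and offset; axial length above 24.2 mm remapped by
  the published quadratic; corneal height from the corneal-width chord;
  retinal thickness $0.65696 - 0.02029\,AL$ added to $AL$; corneal index
  1.333.
* **Holladay 1** — anatomic ACD from the corneal dome with the radius
  floored at 7 mm and the chord $12.5\,AL/23.45$ capped at 13.5 mm, plus
  the published 0.56 mm constant, plus the Surgeon Factor; retinal
  thickness 0.200 mm; corneal index 4/3.
* **Hoffer Q** — the tangent model with degree-valued arguments, the
  short/long-eye correction switching at 23 mm, axial length clamped to
  [18.5, 31] mm inside the ELP expression only, the published −0.99166
  constant, and the 0.05 mm ELP augmentation in the vergence stage;
  corneal power is the keratometry reading itself.
* **Haigis** — $ELP = a_0 + a_1\,ACD + a_2\,AL$ with $a_1 = 0.4$,
  $a_2 = 0.1$ fixed (single-constant optimization practice; both are
  configurable); corneal index 1.3315.

Keratometry is converted to radius with the 1.3375 calibration index
($r = 337.5/K$). Two genuinely open choices were settled as follows. The
Haigis ACD term uses the biometer's epithelium-referenced ACD column, not
aqueous depth; devices differ, so this is a switch (`acd_source`). And
corneal-height square roots are clamped at zero with a warning rather than
an error, because real radius/axial-length combinations can violate the
chord geometry — roughly one eye per few thousand draws at the generator's
truncation bounds.

The Haigis intercept default warrants a note: with slopes fixed at
0.4/0.1, the intercept that corresponds to an A-constant of 119.0 through
the standard conversion is $a_0 = 0.62467 \cdot 119 - 72.434 \approx
1.902$, and that is the package default. Published gender-stratified
intercepts near $-0.74$ for the same lens imply different device-internal
slopes; with 0.4/0.1 such an intercept would place the lens ~2.6 mm too
shallow and no plano-targeted cohort could zero its mean error within a
±1 mm search interval.

## Lens-constant optimization

The optimality criterion is zeroization: the constant at which the mean
signed prediction error, $\overline{SPE}$ with $SPE = \text{predicted} -
\text{observed SE}$, vanishes on the training stratum. Minimizing
$|\overline{SPE}|$ and root-finding $\overline{SPE} = 0$ coincide at the
optimum, but the root formulation is better conditioned, so
`optimize_constant()` brackets the root (Brent's method via `uniroot`)
and falls back to golden-section minimization of the absolute mean error
only when the interval contains no sign change — in which case the result
is flagged `converged = FALSE` with diagnostics, never silently.

Defaults: search half-widths of ±2.0 A-units (SRK/T), ±1.0 mm (Surgeon
Factor, Haigis $a_0$) and ±1.5 mm (pACD) around the starting constants —
an order of magnitude wider than plausible inter-gender differences — and
a convergence tolerance of $10^{-3}$ D on the mean SPE, two orders below
the smallest stratum effects of interest. Optimization uses all training
eyes; the one-eye-per-patient restriction applies to testing only, where
each patient must carry equal weight.

## The cohort pipeline

`run_pipeline()` follows the study design it models: validate records
(each rejection carries a reason; nothing is dropped silently), exclude
prediction-error outliers beyond 1.96 sample SD of the cohort mean in a
single pass under a reference formula (SRK/T by default — the reference is
configurable because the choice is not canonical), split patients 1:1 by a
seeded fair coin with both eyes of a patient on the same side, keep one
random eye per test patient, optimize constants on the training eyes
(pooled and per gender), and evaluate both constant sets on the test eyes.

Group statistics wrap the standard machinery: Wilcoxon rank-sum for
biometry contrasts (exact when both groups are ≤ 25 and tie-free), Welch's
t for prediction-error contrasts, and a paired Wilcoxon signed-rank on
per-eye absolute-error differences for the pooled-versus-stratified
comparison — paired, because both constant sets are evaluated on the same
eyes. The regression of SPE on AL, CCT, ACD, LT, Km, AST, WTW, age and a
male indicator (male = 1) is ordinary least squares with a nested-model F
test for the gender term; OLS matches the continuous outcome and the
coefficient scale of interest. Exact small-sample p-values are verified in
the test suite against full-enumeration oracles (all $\binom{n+m}{n}$
labelings, all $2^n$ sign patterns).

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the analysis needs:

* per-gender truncated-Gaussian marginals for AL, ACD, Km, LT, WTW, CCT,
  AST and age, with defaults at the means/SDs of a large gender-stratified
  cataract population (women ~0.6 mm shorter AL, ~0.12 mm shallower ACD,
  ~0.7 D steeper Km);
* a correlation structure on the (AL, ACD, Km, LT, WTW) block — AL–ACD
  0.45, AL–Km −0.30, AL–WTW 0.25 — chosen as plausible adult-eye values.
  Real correlations in any given cohort are unknown, so calibration claims
  (and the acceptance checks) target the marginals only;
* bilateral patients (default fraction ≈ 0.528, matching an
  eyes-per-patient ratio of ≈ 1.53) whose fellow eyes are redrawn with
  intra-patient correlation 0.9; age is a patient-level draw truncated to
  [40, 100];
* an IOL selection policy: the power that attains the surgeon's target
  (plano by default) under the world formula and true constant, rounded to
  0.5 D with midpoint ties taken toward the higher power (myopic bias);
* observed refraction = world prediction − gender offset $\delta$ +
  $N(0, 0.40^2)$ noise, so the pipeline's SPE equals $+\delta$ in
  expectation for that gender. Offsets enter through the *observed*
  refraction because the phenomenon being modelled — a residual gender
  effect that survives constant optimization — cannot be produced by any
  single-constant mechanism inside the formula itself. Defaults are
  $\delta = 0$; the gender-effect studies use $+0.07$ D (female) and
  $-0.10$ D (male).

It does not emulate astigmatism axes, device measurement error,
non-Gaussian biometry tails, ocular pathology, or surgeon/device effects.
Passing tests therefore demonstrate correctness of the estimation
machinery under a well-specified world, not clinical performance on real
eyes. One consequence visible in the outputs: the 1.96 SD outlier screen
truncates each stratum's SPE distribution toward the pooled center, so
measured stratum means are attenuated relative to the injected offsets —
exactly as screened clinical cohorts attenuate their own tails.

## Numerical choices and degenerate inputs

Lengths are converted to meters exactly once, at the vergence boundary;
ELP models work in mm. Non-physical vergence states (object vergence at
the IOL plane ≤ 0, or a non-positive corneal object distance) raise errors
naming the offending term rather than returning NaN; a degenerate Haigis
constant triple that yields ELP ≤ 0 is caught there. Zero-variance SPE
vectors make the outlier screen a no-op; all-zero paired differences give
p = 1 with a warning. Truncation rejection sampling aborts with a
configuration error if bounds and moments are inconsistent. All
randomness — biometry, bilaterality, eye labels, refraction noise, the
train/test split and the test-eye choice — is seeded, and cohort
generation is byte-reproducible.

## Problem sizes used in the tests

Unit tests run on cohorts of 60–2,600 patients. The end-to-end acceptance
checks use 200,000 eyes per gender for generator calibration (standard
error of the AL mean ≈ 0.003 mm against a 0.02 mm check), 4,000-eye
single-eye worlds for zeroization and constant recovery (recovery within
0.05 constant units; the mean-SPE standard error of ≈ 0.006 D maps through
the local constant-to-SPE slope to ≈ 0.01 A-units), and an 8,000-eye
balanced cohort for the stratified-optimization findings. The whole suite
completes in well under a minute on one CPU.
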