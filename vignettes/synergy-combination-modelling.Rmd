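---
title: "Methods: synergy combination modelling for two-agent cytotoxicity assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy combination modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyrsm)
```

This vignette documents the models behind `synergyrsm`, the assumptions and
tunable parameters of each stage, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
methodology leaves room.

## The analysis chain

The package models a two-extract combination study: a cytotoxic turmeric
extract (TM, active principle curcumin) combined with an essentially
non-toxic black pepper extract (BP, active principle piperine, a known
bioavailability enhancer) against two lung cancer lines (A549, NCI-H292)
and a resistant normal fibroblast line (MRC-5). Five stages:

1. single-agent median-effect fits (`fit_median_effect()`),
2. central composite design + quadratic response surface (`build_ccd()`,
   `fit_quadratic()`),
3. desirability optimization toward the EC50 (`optimize_desirability()`),
4. Chou–Talalay combination-index scoring (`ci_fa_curve()`),
5. blank-corrected consumption kinetics (`consumption_rate()`,
   `cc_activity()`).

`run_pipeline()` executes them in order, writing seeded, fingerprinted CSVs.

## Median-effect dose–response

The median-effect equation `fa/fu = (D/Dm)^m` unifies sigmoidal dose–effect
behaviour in two parameters: `Dm`, the dose for the 50% effect, and `m`,
the shape. It assumes a monotone effect over dose and a well-defined 100%
viability baseline. The fit is ordinary least squares of
`log10(fa/(1−fa))` on `log10 D` (log base 10 throughout, the convention of
the CI literature), after averaging replicates per concentration —
matching the mean-based reporting of plate assays.

Choices worth knowing:

* **EC50 := Dm.** The EC50 is defined as the median-effect dose of this
  fit, keeping the EC50 and the combination-index machinery on one model
  rather than mixing in an interpolation-based EC50.
* **Clamp ε = 1e-4.** `fraction_affected()` clamps `fa` to
  `(1e-4, 1 − 1e-4)` so the logit stays finite on plate readings at or
  beyond 0%/100% viability. Averaged points *on* the clamp (mean viability
  ≥ 100% or ≤ 0%) are excluded from the regression — a clamped logit is an
  arbitrary number and would act as pure leverage; the count is reported
  as `n_excluded`.
* **Usability and non-toxicity.** A fit is `usable` when its slope is
  positive with at least two off-clamp points. Separately,
  `is_nontoxic()` flags agents whose largest observed mean effect stays
  under `fa_threshold = 0.2`: a shallow curve like BP's (≤ ~8% cell death
  at 400 µg/mL) can produce a formally positive slope whose extrapolated
  Dm lies far outside the tested range; treating such a partner as having
  a meaningful single-agent Dx would be spurious. The threshold is an
  argument wherever it matters.

## Central composite design and the quadratic surface

`build_ccd()` encodes the study's design: five uniformly spaced levels per
factor (TM 10–50, BP 200–400 µg/mL), factorial points at the inner levels
(coded ±1), axial points at the extremes, and replicated center points.
Two non-obvious constants:

* **α = 2.** A rotatable CCD would put axial points at ±√2 in coded units,
  which cannot land on a uniformly spaced five-level grid. With α = 2 the
  axial points coincide exactly with the stated extreme concentrations.
* **n_center = 6.** 4 factorial + 4 axial + 6 center = 14 runs, the only
  partition of the stated run count consistent with a two-factor CCD; the
  six center replicates carry the pure-error degrees of freedom.

`fit_quadratic()` fits the full second-order polynomial by least squares
*in coded units* (condition numbers in natural units reach ~1e10 once BP²
enters) and converts the coefficients back to natural units by expanding
the affine substitution; predictions from the two parameterizations agree
to machine precision, which the test suite checks. Diagnostics follow
response-surface practice: residual SS is split into lack-of-fit and pure
error over replicated design points; adequate precision is the
predicted-response range over `sqrt(p·MSE/n)`; CV% is
`100·sqrt(MSE)/mean(Y)`. Rank deficiency (e.g. responses measured along a
single BP level) errors out naming the aliased terms. `predict()` warns on
mild extrapolation (≤ 5% of the factor span beyond the region) and refuses
gross extrapolation — a quadratic fitted on the design region carries no
information beyond it.

Each cancer cell line is fitted as a separate response on the same design.

## Desirability optimization

Each predicted response is transformed by a Derringer desirability
(`desirability_score()`): a two-sided linear ramp peaking at the target
`T = 50%` viability (the EC50 goal), zero outside `[L, U]`. Defaults where
the methodology gives latitude:

* **Bounds `L`, `U`:** the min/max predicted response over the design
  region (`predicted_response_bounds()`), the data-driven default of
  standard DOE software; no fixed bounds are stated by the workflow this
  models.
* **Weights `s = t = 1`:** linear ramps; nothing suggests unequal
  weighting.
* **Combination rule:** the geometric mean, so any unacceptable response
  annihilates the whole combination.

`optimize_desirability()` runs a 201 × 201 grid pass (sub-0.5% resolution
over the region at negligible cost), takes the grid-local maxima,
polishes each by Nelder–Mead, and — when every goal is a target goal with
two responses — finishes with a Newton iteration on the 2×2 system
`Y_i(tm, bp) = T_i`. The Newton step matters: the maximizer of `D` at an
attainable two-target optimum sits on a crease of the (piecewise-linear)
desirability surface, where simplex methods stall at `D ≈ 1 − 1e-7`; the
Newton root is exact to machine precision, so an attainable `D = 1` is
reported as exactly 1. Solutions are deduplicated at 0.5% concentration
resolution and ranked by `D`, with ties broken toward the lower total
concentration — a deterministic, pharmacologically parsimonious order.
An all-zero desirability region returns an empty table with a warning
rather than an arbitrary point.

## Combination index

`combination_index()` evaluates `CI = d1/Dx1(fa) + d2/Dx2(fa)` at each
combination's own observed effect level (non-constant-ratio design — the
modelled study combines a fixed TM dose with varying BP, plus a single
optimum point, not a fixed-ratio dilution series). The non-toxic partner's
term is dropped (`Dx2 → ∞` limit) and flagged `partner_nontoxic`; this is
configurable through the `fa_threshold`, recording rather than resolving
the ambiguity of how CI software treats an inactive arm. Classification
uses an additivity band of ±0.05 around CI = 1 by default (exact unity is
a measure-zero event on real data); the tolerance is an argument.

## Consumption kinetics

`consumption_rate()` regresses signal on time over *all* replicate points
(not replicate means — keeping per-point error weighting), takes `Abs0`
from the regression intercept rather than the earliest measurement, and
reports `σCC = −σAbs·N0/Abs0`, which is invariant to rescaling the signal.
An intercept ≤ 0 is an error (the normalization is then meaningless);
fewer than three distinct time points is an error. `cc_activity()`
subtracts the cell-free blank's rate and normalizes by the initial
compound mass; a negative activity is returned with a warning, not
floored — it is a useful QC signal that the blank decayed faster than the
sample. The default mass normalization is per µg *curcumin*
(`curcumin_mass()`: extract concentration × 26.7 µg curcumin per mg
extract); whether published rates of this kind are normalized per µg
compound or per µg extract is often unstated, so the mass is an explicit
argument everywhere.

## What the synthetic generator emulates — and what it does not

`generator_config()` fixes a ground truth with the structure the analysis
assumes:

* median-effect single-agent curves — A549 (m = 2.0, Dm = 77.8 µg/mL),
  NCI-H292 (m = 2.2, Dm = 92.0), and a resistant MRC-5 (m = 4, Dm = 220,
  so cytotoxicity only appears at the top tested dose of 150 µg/mL);
  slopes in the 2–4 range typical of extract cytotoxicity assays;
* a near-flat BP curve ramping linearly to 8% effect at 400 µg/mL;
* quadratic combination surfaces for the two cancer lines whose 50%
  contours cross at an interior point of the design region
  (TM 48.5, BP 241.7 µg/mL) — the A549 surface predominantly TM-driven,
  the NCI-H292 surface predominantly BP-driven, so the crossing is
  transversal and well-conditioned;
* linear compound decay whose per-condition slopes are *derived from*
  target consumption activities (TM 116.14 / 76.02, TMBP 49.72 / 47.53
  nmol/h/µg on A549 / NCI-H292, blank 10 nmol/h), so the kinetics chain
  recovers the configured activities exactly in the noiseless limit;
  `N0 = 2000` nmol and an initial signal of 100 units keep every series
  positive over the 10 h window.

Replicate noise is multiplicative Gaussian (`CV = 0.05`, 3 replicates by
default), truncated to the plate-reader range [0, 120]% — assay scatter
scales with signal, and mean ± SD reporting gives no basis for a richer
error model. Every generator draws from a substream derived from the one
seed, so identical configurations give bit-identical tables and the
session RNG is left untouched.

Not emulated: plate-layout and edge effects, heteroscedasticity beyond the
multiplicative model, chromatographic peak shapes or absorbance
nonlinearity, and any systematic lack of fit of the true combination
response to a quadratic. Passing tests therefore demonstrate correctness
of the estimators under the assumed generative structure — not robustness
to real-plate artifacts.

One behaviour worth understanding: the ground-truth optimum sits 1.5 µg/mL
from the TM = 50 edge of the design region. Under the default noise, the
*fitted* 50%/50% contour crossing occasionally lands just outside the
region, in which case the constrained optimum is correctly reported as a
boundary point with `D` slightly below 1 — the right inference for that
realization, and a faithful reproduction of how fragile near-edge optima
are in this workflow.

## Problem sizes

All defaults are desk-scale: 14-run designs (×3 replicates in the
pipeline), six-point dose grids, five-point time courses, 200-seed
bias checks, 500-repeat coefficient Monte Carlo, and a 2000 × 2000
desirability grid oracle in the tests. The full test suite runs in about
ten seconds; a pipeline run takes under two seconds.

## Known limitations

* Only two-factor CCDs; no Box–Behnken or D-optimal designs, no stepwise
  term reduction.
* No 4PL/5PL logistic or Bayesian dose–response alternatives; the
  median-effect logit-OLS fit weights all averaged points equally.
* No dose-reduction index, isobologram, or Bliss/Loewe/HSA alternatives to
  the combination index.
* Kinetics are strictly linear (zero-order); no Michaelis–Menten
  saturation.
* The desirability search assumes box bounds only — no joint constraints
  between the factors.
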