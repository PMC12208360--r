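---
title: "Compositional multilevel analysis of work-time physical behaviours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional multilevel analysis of work-time physical behaviours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codatime)
```

## The problem

During a workday a person's time splits into sedentary behaviour (SB),
light physical activity (LPA) and moderate-to-vigorous physical activity
(MVPA). These three durations are not three free variables: they share a
fixed total, so spending more time in one behaviour necessarily takes
time from the others. Data of this kind carry only *relative*
information and are compositional — the appropriate sample space is the
simplex, not R³. Treating the parts as independent outcomes produces
spurious correlations and predictions that can leave the simplex.

`codatime` analyses such work-time behaviour compositions measured on
workers who are nested in teams, which are nested in institutions (the
design of multi-site occupational accelerometry studies, e.g. childcare
or eldercare settings). The two scientific questions it addresses are:

1. *Where does the variation live?* How much of the between-worker
   variability in behaviour compositions is attributable to the
   institution, the team, and the worker level?
2. *What is it associated with?* Which measured determinants — worker
   demographics, health, psychosocial factors, team structure,
   institutional characteristics — are associated with the composition?

## Log-ratio coordinates

A three-part composition $(x_{SB}, x_{LPA}, x_{MVPA})$, closed so the
parts sum to 1, is mapped to two unconstrained coordinates by an
isometric log-ratio (ilr) transformation under the sequential binary
partition {SB} vs {LPA, MVPA}, then {LPA} vs {MVPA}:

$$
z_1 = \sqrt{\tfrac{2}{3}}\,\ln\frac{x_{SB}}{\sqrt{x_{LPA}\,x_{MVPA}}},
\qquad
z_2 = \sqrt{\tfrac{1}{2}}\,\ln\frac{x_{LPA}}{x_{MVPA}}.
$$

$z_1$ is the sedentary-versus-active trade-off; $z_2$ contrasts light
against moderate-to-vigorous activity. The map is an isometry (Aitchison
distances become Euclidean distances), is scale invariant, and inverts
exactly, so model predictions on the coordinate scale can always be
carried back to behaviour shares:

```{r}
x <- closeComposition(c(3.17, 2.66, 0.82)) # hours -> shares
z <- ilrTransform(x)
round(z, 4)
round(inverseIlr(z), 4)
```

*Pivot coordinates* re-express the same geometry with any chosen
behaviour rotated into first position, so that the first coordinate
contrasts that behaviour against the geometric mean of the other two.
The rotation preserves the norm of the coordinate vector; it changes
which contrast is read off, not the information content.

A coefficient $\beta$ on a first pivot coordinate (per unit of a
determinant) translates into a percentage change of the pivot behaviour
relative to the remaining behaviours,

$$
100\left(e^{\beta\sqrt{D/(D-1)}} - 1\right)\%, \qquad D = 3,
$$

which undoes the $\sqrt{(D-1)/D}$ normalisation of the coordinate and
exponentiates the log-ratio shift. For example
`percentChange(0.03)` = `r round(percentChange(0.03), 1)`% and
`percentChange(-0.05)` = `r round(percentChange(-0.05), 1)`%.

### Zero handling

A measured day can contain no MVPA at all, and a log-ratio of zero is
undefined. `replaceZeros()` applies multiplicative replacement: a zero
in part $j$ becomes $\delta_j$ = half the smallest nonzero closed
fraction observed for that part in the dataset, and the remaining parts
of that row are rescaled so it still sums to 1. This is the standard
conservative device in compositional analysis: it keeps log-ratios
finite while leaving non-zero rows untouched. The replacement value is
data-driven rather than fixed, so very precise datasets get
proportionally small imputations.

## From daily records to analysis rows

Accelerometer studies record several workdays per worker.
`preprocessStudy()` turns the day table into one analysis row per
worker:

* **Validity rule.** A day is valid if it holds at least 4 h of
  work-time measurement (`min_work_hours`, a closed bound: exactly 4 h
  counts). Workers left with no valid day are excluded and reported,
  never silently dropped.
* **Aggregation.** Each valid day is closed to a composition
  (with zero replacement) and the worker's composition is the
  *geometric-mean* composition of their daily compositions — the
  compositional centre, equivalent to averaging on the ilr scale. This
  matches the use of geometric means in the descriptive summaries. An
  arithmetic mean of the daily compositions is available
  (`aggregation = "arithmetic"`) as a sensitivity analysis; whether
  day-to-day variation should instead enter the models as a fourth
  hierarchical level is a design question we deliberately close by
  fixing the three-level model on worker-aggregated data.
* **Complete cases.** The association models use only workers with all
  required determinants observed (`completeCaseFilter()`), with
  per-determinant attrition counts attached; no imputation is done.

## The multilevel models

### Variance components

`fitVca()` fits, by REML, a linear mixed model to the two ilr
coordinates *jointly*: the coordinates are stacked as repeated outcomes
with a fixed mean per coordinate and random intercepts for
institution-by-coordinate and team-by-coordinate, sharing a single
variance parameter per organisational level across the two coordinates.
Worker-level variance is the residual. This pooling yields one variance
estimate and one percentage contribution per level — the natural
three-number summary of "where the variation lives" — while a
per-coordinate decomposition is attached as a diagnostic
(`$per_coordinate`).

Estimation is delegated to `lme4::lmer` with the `bobyqa` optimiser and
a tight final trust-region radius (`rhoend = 1e-10`); on balanced
designs the resulting REML estimates reproduce the closed-form
expected-mean-squares ANOVA estimators to about `1e-8`, which the test
suite verifies against an independently coded oracle. Negative variance
solutions cannot occur: the REML parameterisation constrains components
to be non-negative, so null components land on the boundary at 0.

Two degenerate designs are refused rather than silently fitted: if
every team has a single worker the team component is confounded with
worker-level variance, and if every institution has a single team the
team and institution components are confounded.

### Association models

`fitModel1()` is the primary association model: each ilr coordinate is
regressed on all 15 determinants as fixed effects with nested random
intercepts (institution, team within institution), by REML.
Conventions:

* Determinants enter on their raw scales, so coefficients are per-unit
  effects (per year of age, per point of exertion, etc.); no
  standardisation.
* Reference levels: male (sex), pedagogue (job type), private
  (institution type).
* Each determinant receives one composition-level p-value from a
  2-degree-of-freedom joint Wald test of its two per-coordinate
  coefficients, treating the coordinate fits as independent (the
  coordinates are orthogonal contrasts, and in the generator their
  errors are independent; the type-I-error simulation in the test suite
  checks the size of this test under the null). Per-coordinate
  estimates, Wald 95% CIs and p-values are always reported alongside,
  because a single printed p per determinant is otherwise ambiguous.
* p-values use the large-sample Wald normal approximation; no
  Satterthwaite or Kenward–Roger degrees-of-freedom correction is
  applied, and no multiple-testing adjustment is made (each determinant
  is tested at the 5% level). With few top-level clusters the test for
  institution-level determinants is therefore slightly liberal; this is
  a documented limitation.

`fitPivotModels()` refits the same structure three times with each
behaviour's first pivot coordinate as the outcome, quantifying how each
determinant relates to that behaviour's *dominance* over the other two;
every coefficient is translated into a percentage change via
`percentChange()`. The SB-pivot model is mathematically the same
regression as the ilr1 equation of the primary model, which the test
suite exploits as a consistency check.

`predictCompositionCurve()` evaluates the primary model along a grid of
one determinant, holding other determinants at their sample mean (or
most frequent level) and random effects at zero, and maps the predicted
coordinates back through the inverse ilr — the long table it returns
(value, sb, lpa, mvpa) is ready for ternary plotting. Grids beyond the
observed determinant range warn rather than fail.

## The synthetic-data generator

No public dataset of this design exists, so the generator *is* the
package's test bed and defines the study conditions under which every
downstream claim is verified. `simConfig()` encodes a multi-site
occupational study:

* **Hierarchy.** 16 institutions; 4–5 teams per institution (uniform);
  2–4 workers per team with probabilities (0.60, 0.35, 0.05) — in
  expectation 72 teams and about 176 workers, matching a realistic
  multi-site occupational sample.
* **Outcome model.** For each coordinate,
  $z = \bar z + X\beta + u_{inst} + u_{team} + e_{worker}$ with
  independent mean-zero Gaussian intercepts. Default variances per
  coordinate are 0.079 (worker), 0.0017 (team), 0.0021 (institution) —
  a hierarchy in which ~95% of variation sits at the worker level. The
  grand-mean composition is (0.4767, 0.4000, 0.1233). Default nonzero
  effects: physical exertion −0.03 on $z_1$ and maximal pain intensity
  +0.03 on $z_1$; all effects on $z_2$ default to zero because no
  coordinate-resolved target exists for it. Determinants are centred at
  their configured means when forming $X\beta$, so the grand-mean
  composition remains the population centre regardless of which effects
  are switched on.
* **Determinants.** Marginal means/SDs and admissible ranges follow the
  catalogue in `determinantCatalogue()` (11 worker-level, 2 team-level,
  2 institution-level variables). Continuous determinants are truncated
  normals whose underlying parameters are *moment-matched by quadrature*
  so the realised truncated mean equals the target mean exactly; the SD
  is matched as closely as the family allows. For pain interference
  (target mean 3.5, SD 6.6 on [0, 28]) no truncated normal attains both
  moments — a decreasing log-concave density cannot have SD nearly twice
  its mean on this support — so the realised SD (~3.5) is smaller than
  the target while the mean is exact; the mean is prioritised because
  location is what the effect-size conventions depend on. Determinants
  are simulated independently (no copula); only marginals are targeted.
* **Days.** Each worker contributes 1–5 measured days with
  probabilities (0.10, 0.15, 0.25, 0.35, 0.15), mean 3.3. Daily work
  duration is lognormal around a geometric mean of 6.61 h with
  `sdlog = 0.25`, chosen so that roughly 2% of days fall below the
  4-hour validity threshold and the filter has real work to do. Day
  compositions scatter around the worker's with an ilr-scale SD of 0.1
  per coordinate; this day-level spread is a modelling placeholder, not
  an empirical estimate — between-day within-worker variability is not
  a quantity the defaults are calibrated to.
* **Missingness.** Worker-level questionnaire determinants are masked
  independently at rate 0.0125 each, so about 87% of workers are
  complete cases — emulating the attrition from accelerometer-valid
  samples to model-ready samples in such studies.
* **Determinism.** The same configuration and seed reproduce the
  dataset byte for byte; every stochastic entry point takes a seed.

What passing tests on this generator do *not* show: robustness to
correlated determinants, to non-Gaussian random effects, to informative
missingness, or to day-level structure beyond exchangeable noise. Those
are properties of real data the generator intentionally does not
emulate.

## Verification strategy and problem sizes

The test suite verifies, among others:

* closure, zero-replacement, ilr/inverse-ilr round-trips (tolerance
  1e-10), scale invariance, pivot-norm invariance and the
  Aitchison-distance isometry on 1000 random compositions;
* the percentage-change closed form against hand-evaluated values;
* REML-vs-ANOVA oracle equivalence on balanced designs (tolerance
  1e-6, achieved ~1e-8);
* parameter recovery at the default study size: over 50 replicated
  studies the mean worker-level contribution falls in [90, 99]% (the
  truncation of null-ish team/institution components at zero biases
  their mean contributions slightly upward, which is why the band is
  asymmetric around the generating value), and with 100 institutions
  (~1000 workers) the mean recovered exertion coefficient is within
  ±0.01 of the generating −0.03;
* the size of the 2-df joint Wald test: with all effects zero, the
  pooled rejection rate at the 5% level over 500 replicated studies
  stays within [0.02, 0.08].

Replicate counts (50 for recovery, 500 for test size) balance
Monte-Carlo precision against the suite's runtime; they are stated here
as the package's own verification choices.

## Known limitations

* Wald-z inference without small-sample df corrections is liberal for
  determinants measured at the institution level (16 clusters).
* The joint test assumes independence between the two coordinate fits
  rather than estimating their cross-coordinate covariance.
* The variance decomposition pools one variance per level across the
  two coordinates; heterogeneity between coordinates is surfaced only
  through the per-coordinate diagnostic.
* Aggregating days compositionally before modelling discards
  within-worker day-to-day variance rather than modelling it as a
  fourth level.
* The generator draws determinants independently; effects of
  collinearity among real determinants on the models are untested.
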