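---
title: "Vector-based comparison of correlated pharmacokinetic endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector-based comparison of correlated pharmacokinetic endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bioequivalence trials compare a test (T) against a reference (R) drug
product with two co-primary pharmacokinetic endpoints: the area under the
concentration--time curve (AUC, extent of absorption) and the maximum
observed concentration (Cmax, nominally the rate of absorption). These
endpoints are correlated -- Cmax carries a large extent component -- so the
study analyzes partly the same attribute twice. A steeper summary of the
absorption phase, the average slope (AS: the mean of the successive chord
slopes of the rising limb up to the first Cmax), tracks the absorption rate
much better than Cmax but is noisy, and a noisy endpoint costs statistical
power under the 80--125% confidence-interval inclusion rule.

Vector-based comparison (VBC) treats each endpoint measured across the K
subjects of a trial cell as a vector in K-dimensional space. After
z-scoring, the cosine of the angle between a secondary endpoint and a
pre-declared anchor endpoint (E1, here AUC) equals their Pearson
correlation; the secondary endpoint is then projected onto the axis
perpendicular to the anchor,

$$ B_y = B \cdot \sin\theta, \qquad
   \cos\theta = \frac{A\cdot B}{\lVert A\rVert\,\lVert B\rVert}, $$

and only the anchor and the perpendicular components enter the regulatory
statistics. Orthogonal vectors are independent: the projection retains the
part of each endpoint that says something AUC does not already say.

## What the package implements

* `sim_pk`-style trial simulation: one-compartment and lagged
  two-compartment oral models in closed form (`pk_model()`,
  `predict_concentration()`; `method = "ode"` integrates the mass-balance
  equations with deSolve as a cross-check, and the two routes agree to a
  relative 1e-6 in the test suite). Lognormal between-subject and
  within-subject (inter-occasion) random effects on every structural
  parameter, with `sd = sqrt(log(1 + CV^2))`, plus proportional residual
  error clamped at zero (`simulate_trial()`).
* Non-compartmental endpoints (`build_endpoint_table()`): linear
  trapezoidal AUC to the last positive sample; terminal slope by log-linear
  regression starting from the last three points strictly after Tmax and
  extending earlier while the adjusted R-squared does not decrease (never
  including Tmax); AUCinf with the observed Clast; first-occurrence Tmax;
  mean-chord-slope AS with a pluggable strategy.
* The VBC transform (`vbc_transform()`): per period-by-treatment cell,
  z-score the endpoint and the anchor, take the angle, multiply the raw
  values of the cell by its `sin(theta)`. Angles live in `[0, 180]`
  degrees, sines in `[0, 1]`, and a sine below `1e-6` marks a degenerate
  (anti)parallel endpoint whose perpendicular component is empty.
* Regulatory statistics (`anova_2x2()`, `ci90_decision()`): fixed-effects
  ANOVA of the log endpoint on sequence, subject-within-sequence, period
  and treatment; for balanced complete data this is computed by the exact
  period-difference closed form (residual df `n - 2`), verified against a
  brute-force `lm()` fit to 1e-8 in the tests; 90% CI
  `exp(effect ± t(0.95, df) * sqrt(mse (1/n1 + 1/n2) / 2))`; acceptance if
  the unrounded interval sits inside 80--125%.
* Monte Carlo power (`power_sweep()`): acceptance percentages and
  geometric-mean GMRs per endpoint and per co-primary pair over a grid of
  absorption-rate ratios KaT/KaR, the test product's ka being the scaled
  one. Seeds follow a counter ladder (master, +10000 per grid point, +1 per
  trial) so any single trial is reproducible in isolation.
* PCA of the five endpoints (`run_pca()`): eigendecomposition of the
  correlation matrix of the z-scored endpoint matrix, components ordered by
  eigenvalue, eigenvector signs fixed by making the largest-magnitude
  loading positive, biplot angles via `loading_angles()`.

## Study conditions and defaults

| Parameter | Default | Why |
|---|---|---|
| subjects per trial | 24 (12 per sequence) | standard mid-size 2x2 study |
| between-subject CV | 15% | typical population variability |
| within-subject CV | 20% | typical inter-occasion variability |
| residual error CV | 5% | small proportional assay error |
| trials per grid point | 1000 | Monte Carlo resolution ~1 point |
| KaT/KaR grid | 1.0--2.0 by 0.1 | 0--100% absorption-rate discrepancy |
| anchor endpoint | AUC | the undisputed extent endpoint |
| PCA cohort | 200 subjects, single occasion | exploratory, pre-crossover |

Three bundled parameter sets (`drug_profile()`) span the absorption
spectrum. They are synthetic surrogates -- not literature estimates --
calibrated once so the noiseless peak falls where the corresponding drug
class peaks: "amlodipine" (one-compartment, Tmax 5.2 h, 144-h sparse
schedule), "irbesartan" (two-compartment with 0.25 h lag, Tmax 1.1 h,
dense early sampling to 48 h) and "hydrochlorothiazide" (two-compartment
with 0.4 h lag, Tmax 2.5 h). Sampling schedules are package choices fitted
to the kinetics; they are not part of any reference dataset.

What the generator emulates: balanced 2x2 crossover exposure data with
realistic lognormal parameter variability, no carryover (complete washout),
and small proportional measurement error. What it does not emulate:
below-quantification-limit censoring, dropouts or incomplete subjects,
correlated random effects between parameters, nonlinear kinetics, and
multiple-dose accumulation. Green simulation-based tests therefore say the
machinery is correct under these idealized conditions, not that the same
percentages would be observed on real assay data.

## Numerical choices

* Closed-form model evaluation everywhere; the ODE route exists for
  verification only. The flip-flop degeneracy (`ka` equal to `k10` or to a
  disposition macro-rate) is rejected at model construction.
* Cosines are clamped to `[-1, 1]` before `acos` (floating-point
  overshoot), Tmax ties break to the earliest time, zero concentrations are
  excluded from the terminal regression, and negative simulated
  concentrations are clamped to zero.
* Zero-variability cells are constant vectors: they have no angle, so
  decomposed endpoints are reported as degenerate rather than silently
  passed through (the raw endpoints still pass at 100% for identical
  products, which is what the identity check asserts).
* The boundary size of the CI-inclusion rule is checked by direct
  simulation at a true GMR of 1.25 with 20% within-subject CV: the
  empirical acceptance is ~5%, the nominal one-sided level.

## Design choices where the method description is open

**Order of transforms.** A pipeline that standardizes and then
log-transforms is not executable literally, because z-scores are negative
for half the subjects. The package therefore uses z-scores *only* to
estimate angles; the projection multiplies the *raw, positive* endpoint
values by `sin(theta)`, and the log transform is applied downstream by the
crossover ANOVA. This is the only reading under which the projection
formula, the decomposed-endpoint comparisons and the log-scale ANOVA can
all be executed as stated.

**Angle granularity.** Angles are estimated within each of the four
period-by-treatment cells and each observation is scaled by its own cell's
sine (the literal reading of repeating the estimation per period and
treatment). `vbc_config(pooling = "pooled")` estimates a single angle per
endpoint instead, as a sensitivity analysis.

**A consequence worth knowing.** In a balanced 2x2, the cell means are
fully parameterized by sequence, period and treatment, so multiplying every
value of a cell by a constant changes neither the residual mean square nor
the CI width; it shifts the estimated treatment effect by half the
log-ratio of the T-cell sines to the R-cell sines, a mean-zero random
quantity when the correlation structure does not depend on treatment. Under
the per-cell reading, decomposition therefore leaves the power of a
decomposed endpoint essentially at the raw endpoint's power, minus the
angle-estimation noise (K = 12 per cell); under the pooled reading the
cancellation is exact and the decomposed decision coincides with the raw
one. The package's power sweeps measure exactly this: variance compression
on the natural scale (`var(B_y) = sin^2(theta) var(B)`, which the tests
verify) does not translate into a narrower log-scale confidence interval
when the compression is a per-cell constant. Claims that the projection
increases crossover power require the cell standardization scale itself to
enter the analyzed values, which the executable reading above deliberately
does not do; the corresponding study-condition checks in
`tests/testthat/test-acceptance.R` are expected to read red and are kept
as measurements, not assertions.

**PCA input.** One observation per subject: reference-product,
single-occasion endpoints of a 200-subject cohort, since the exploratory
dimension-reduction step precedes the crossover comparison. Raw (not
log) endpoints are z-scored by default; `ln = TRUE` toggles.

## Problem sizes

The default suite simulates three full sweeps (3 profiles x 11 grid points
x 1000 trials of 24 subjects) in about a minute in total, a 10,000-trial
boundary-size simulation, and a 200-subject PCA cohort; these sizes are the
package's chosen study conditions, matching the defaults above.

## Known limitations

* The average-slope definition (mean chord slope from the origin to the
  first Cmax) is one of several published variants; `average_slope()`
  accepts a custom strategy function for alternatives.
* No below-quantification-limit rule is modeled; profiles are used as
  simulated.
* Only single-dose, two-period, two-sequence designs; no replicate or
  parallel designs, no scaled-average bioequivalence, no Tmax inference
  (Tmax is computed, never CI-tested).
* The bundled drug profiles are calibrated surrogates; absolute acceptance
  percentages at interior grid points depend on the true (unpublished)
  parameter values and should be read as patterns, not point predictions.
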