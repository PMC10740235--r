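---
title: "Methods: trial-based cost-utility analysis with family clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis with family clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuakit)
```

## The evaluation problem

cuakit implements the economic-evaluation chain for a two-arm randomized
trial in which children and adolescents are nested in families, families are
randomized as a unit, and both resource use and health-related quality of
life are assessed at four waves — baseline and 6, 12 and 18 months — each
covering the preceding 6-month recall window. The comparison is an
intervention arm (INT) against treatment as usual (TAU), from the
perspective of a health and social care system: the costed categories span
inpatient and outpatient treatment, institutional and ambulant child/youth
welfare, medication, and school-based services.

Three structural features drive every methodological choice:

* **Clustering.** Siblings share environment and exposure, so children
  within a family cannot be treated as independent. All variance
  estimation — sandwich standard errors and bootstrap resampling — uses
  the family as the unit.
* **Skewed, zero-heavy costs.** Six-month service costs have standard
  deviations several times their means and a large point mass at zero.
  Normal-theory intervals are therefore supplemented by a nonparametric
  cluster bootstrap, and a gamma GLM serves as a sensitivity model.
* **Dropout.** Attrition approaching half the sample by the final wave is
  handled by last observation carried forward (LOCF) after restricting to
  participants with complete baseline data.

## Cost and QALY summaries

With four 6-month cost measures $C_{t0},\dots,C_{t3}$ per participant, the
annual summaries are

$$\text{annual cost}_{\text{total}} = \frac{C_{t0}+C_{t1}+C_{t2}+C_{t3}}{2},
\qquad
\text{annual cost}_{y1} = C_{t0}+C_{t1},
\qquad
\text{annual cost}_{y2} = C_{t2}+C_{t3},$$

so the identity $\text{total} = (y1+y2)/2$ holds by construction — the code
computes the total from the two year values so the identity is exact in
floating point as well, and the test suite asserts it with `identical()`.
Because the baseline window precedes randomization, the 24-month average is
partly inert to any intervention effect; the per-year summaries exist to
compensate, and the intervention's own delivery cost is booked into year 1
only (`add_intervention_cost()`).

QALYs are the area under the utility curve with two assessments per year,
each worth 0.5 QALYs: the annual QALY is the plain mean of the wave
utilities, and per-year QALYs the means of their two waves. A trapezoid
variant (`compute_qalys(method = "trapezoid")`) is available but is not the
default: the plain mean is the convention the annualization formulas above
imply, and the two differ only through half-weighting of the endpoint
waves. Utilities come either directly from the data or through an additive
instrument-to-utility mapping (`map_to_utility()`); no published tariff
coefficients are bundled — the mapping is a user-supplied table, and the
bundled `utility_mapping_synthetic.csv` is a synthetic placeholder for
format and tests only. Whether mapped utilities should be clamped is
instrument-specific, so the clamp range is an argument (default
`[-1, 1]`, i.e. effectively off).

## Missing data

The chain is intention-to-treat with two rules:

1. `filter_baseline_complete()` removes participants missing baseline cost
   or baseline utility (there is nothing to carry forward), reporting
   per-arm exclusion counts.
2. `locf_impute()` replaces each missing wave value with the participant's
   most recent observed value of the *same* variable — per cost category
   and per utility, not just totals, so category tables stay internally
   consistent after imputation; totals are recomputed afterwards. If a wave
   has some categories observed and others missing, only the missing ones
   are carried forward. Observed values are never altered, imputation is
   idempotent, and imputed cells keep an `imputed` flag.

Zero use and missingness are different things in a retrospective service
inventory: a family that was assessed and used nothing has zero cost; a
family that missed the assessment has missing cost. The CSV dialect makes
this explicit — an assessed participant-wave carries at least one
service-use row (`assessed = 1`, possibly with `units = 0`), while a wave
with no rows, or rows flagged `assessed = 0`, is missing.

LOCF is a strong assumption (stable post-dropout trajectories) and the
package deliberately implements nothing else — no multiple imputation, no
mixed-model handling — because the chain is meant to reproduce this exact
analysis recipe; the generator's MCAR dropout is the one regime where LOCF
is unbiased for means, which is what makes the null-calibration tests
interpretable.

## Incremental estimation

`estimate_difference_ols()` regresses the outcome on an intercept and an
intervention indicator; with a single binary regressor the coefficient
equals the raw difference in arm means exactly (tested as an identity), and
both are reported. Uncertainty comes from the cluster-robust sandwich

$$\widehat{V} = (X'X)^{-1}\Big(\tfrac{G}{G-1}\sum_{g=1}^{G} X_g'e_g\,e_g'X_g\Big)(X'X)^{-1},$$

with families as clusters. The $G/(G-1)$ (CR1) scaling is the conventional
small-sample default at around two hundred clusters; the computation is
delegated to `sandwich::vcovCL(type = "HC0", cadjust = TRUE)` and verified
in the tests against a closed-form oracle written out from the definition,
to 1e-10. p-values use a normal reference by default (alpha 0.05
throughout); a $t_{G-1}$ reference is an option. With both arms present,
at least two clusters in total are required — one arm may consist of a
single family, as in the 6-observation micro-instance the oracle tests
use, though bootstrap resampling is then fragile (see below).

`bootstrap_ci()` implements the nonparametric cluster bootstrap: families
are drawn with replacement from the pooled family list, every child of a
drawn family enters (repeatedly for repeated draws), the arm difference is
recomputed per replicate, and the percentile 2.5/97.5 interval is returned
(default B = 2000). Percentile, not BCa: no refinement beyond "bootstrap
the 95% CI" is implied by the recipe. A resample containing a single arm
contributes no difference; such replicates are discarded and counted, with
a warning above 1% — negligible at trial scale, common for toy fixtures
with a handful of families.

`estimate_difference_glm()` fits a gamma GLM as the skewness sensitivity
model. The link is log: a logit link is undefined on unbounded positive
costs, so log is the only coherent reading of a "gamma family with
logistic link" recipe, and the pairing is standard for cost regressions.
Gamma support excludes zero, so when zeros are present a configurable
offset (default 1 EUR) is added to all costs for this fit only. The
coefficient is reported on the log (ratio) scale together with the
marginalized EUR difference; for the intercept-plus-indicator model the
implied ratio is exactly the ratio of arm means, so the marginalized
difference coincides with the OLS delta — a useful internal cross-check.
The IRLS weights for this family/link are identically 1, which is what
makes the hand-rolled IRLS oracle in the tests a genuinely independent
five-line implementation.

## The decision-analytic layer

`icur_point()` computes the incremental cost-utility ratio
$\Delta C/\Delta E$ and its location on the cost-effectiveness plane.
Both the EUR/QALY scale and the EUR per 0.001 QALY rescaling (ratio /
1000) are always reported, because group-level QALY differences of a few
thousandths put published point estimates on the rescaled axis.
Deterministic tie rules: $\Delta E = 0$ is assigned to the positive-effect
side, $\Delta C = 0$ to the cost-saving (south) side, and a zero QALY
difference flags the ratio undefined rather than dividing.

`bootstrap_cloud()` resamples families once and recomputes *both* deltas
on each resample, preserving the joint distribution — the cloud on the
plane is the object everything downstream consumes. `ceac()` estimates the
probability of cost-effectiveness at willingness-to-pay $\lambda$ as the
fraction of replicates with $\lambda\,\Delta E_b - \Delta C_b > 0$;
replicates exactly at zero count as not cost-effective. The default
$\lambda$ grid is 0 to 125,000 EUR/QALY in steps of 1,000. The CEAC is
nondecreasing in $\lambda$ exactly when every replicate has
$\Delta E_b \ge 0$; with mixed signs it need not be monotone, which the
property tests respect.

`nmb_regression()` regresses each participant's net benefit
$\lambda\,q_i - c_i$ on the intervention indicator per grid point, with the
same cluster-robust machinery; the 95% band is estimate ± 1.96 robust SE.
The curve is affine in $\lambda$ — slope $\Delta E$, intercept
$-\Delta C$ — so its zero crossing is exactly $\Delta C/\Delta E$, tying
the NMB, CEAC and ICUR views together (tested as an identity).

Interval statements about the ICUR itself use the net-benefit duality: a
value $\lambda^\*$ lies inside the bootstrap interval exactly when the
fraction of replicates with positive net benefit at $\lambda^\*$ lies in
(0.025, 0.975). Raw quantiles of the ratio $\Delta C_b/\Delta E_b$ are
sign-unstable when $\Delta E_b$ straddles zero; the duality avoids that
without changing what is being asserted.

## The synthetic generator

`generate_trial()` emulates the statistical structure the chain assumes,
not any clinical mechanism. Defaults (all overridable via
`trial_config()`):

* 105 families per arm, 1 or 2 children each with probabilities 0.4/0.6
  (mean 1.6), family-level randomization.
* Six-month category costs from a two-part model: Bernoulli any-use
  (category-specific probabilities 0.05–0.25, chosen so rare expensive
  categories — inpatient, institutional welfare — are rare) times a
  lognormal positive part whose parameters are solved from the target
  marginal mean and SD, so configured moments hold exactly in expectation.
  Default targets: means (791.57, 206.06, 224.45, 131.10, 19.89, 518.18)
  EUR with SDs (3808.48, 579.93, 1862.13, 529.56, 157.56, 2306.12) —
  SD ≫ mean in every category, the regime that motivates the two-part
  form. Infeasible mean/SD/use-probability combinations are rejected at
  configuration time.
* Utilities normal around 0.76 (SD 0.07), truncated to [0, 1]; at ~3.4
  SDs from the bound the truncation bias is negligible.
* A standard-normal family effect takes fraction `icc` (default 0.3) of
  each outcome's variance (log-scale for costs). No intraclass correlation
  is published for either outcome; 0.3 is a moderate within-family
  correlation typical of psychosocial outcomes, and it is a config value,
  not a calibrated one. The cost and utility family effects are drawn
  independently: the generator encodes no cross-outcome correlation, which
  is exactly the condition under which a null trial's bootstrap cloud is
  quadrant-uniform in the aggregate.
* Treatment effects enter at post-baseline waves only (the baseline recall
  window precedes randomization): INT costs at t1–t3 are scaled by a
  common factor, and INT utilities shifted by a constant, chosen so the
  expected differences in the *annual totals* equal the configured
  `delta_cost` and `delta_qaly` exactly. Defaults are zero — a null trial.
* Missingness completely at random: ~3% baseline missingness (the
  baseline filter's target), then monotone dropout with per-wave hazards
  calibrated so roughly 29/53/53% of participants need imputation at
  t1/t2/t3. The third-wave hazard is zero because the target missingness
  profile is essentially flat between the last two waves and monotone
  dropout cannot decrease.

Every trial carries a `ground_truth` attribute (true effects, planted
missing sets, dropout waves) so recovery and filtering tests assert
against the generator's own record rather than re-deriving it.

What the generator does *not* emulate: time trends in costs or utilities,
cost–utility correlation within participant or family, informative
(MNAR) dropout, item-level service-use behaviour (an item-level mode
exists purely to exercise the pricing path), or any clinical trajectory.
Passing tests therefore demonstrate that the chain is correct and
calibrated under clustering, skewness, zero-inflation and MCAR dropout —
not that LOCF or the percentile bootstrap are robust to informative
missingness or heavier tails than the lognormal.

## Numerical and testing choices

* Costs are carried at full floating precision; only reports round to
  cents.
* Seeds are explicit everywhere randomness exists (default 20151201);
  identical seeds give byte-identical outputs, asserted in the tests.
* The null-calibration suite uses 400 replicate study-sized null trials
  with B = 500 bootstrap replicates each: 200 for CI coverage of zero,
  all 400 for the pooled cost-effectiveness-plane quadrant shares. A
  single trial's quadrant share is approximately uniform on (0, 1) over
  repeated trials (probability integral transform), so shares are only
  informative pooled; 400 trials put the Monte-Carlo error of each mean
  share near 0.011, comfortably inside the ±0.03 assertion.
* Parameter recovery uses one 500-family-per-arm trial (tight
  delta-method check on the NMB zero crossing) plus 50 study-sized
  replicates for the ICUR-interval coverage check.
* Degenerate inputs are exercised deliberately: constant outcomes
  (sandwich SE exactly 0), within-arm-constant data (bootstrap cloud
  collapses to a point), zero-variance generator configs (all
  participants identical), empty retained sets and baseline gaps (hard
  errors).

## Known limitations

* LOCF only; no multiple imputation or longitudinal modelling.
* No covariate adjustment — the incremental models contain only the arm
  indicator, matching the analysis recipe being reproduced.
* No discounting (24-month horizon) and no multi-comparator support.
* The gamma GLM's zero-offset is a pragmatic device; two-part inference
  models are out of scope.
* Published group-level results can only be checked through arithmetic
  identities on printed inputs (the underlying trial data are not
  shareable); distributional claims are validated on synthetic data only.
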