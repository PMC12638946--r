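---
title: "Auditing clinical risk models for threshold artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing clinical risk models for threshold artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical protocols discretize continuous biomarkers at memorable round
numbers: treat above a creatinine of 3.5 mg/dL, replete fluids above a
sodium of 150 mEq/L. Because the patients selected by such a rule then
receive an effective treatment, the *observed* risk of the treated group
falls below their intrinsic biological risk. A risk model fitted to
observational data therefore learns a blend of biology and practice, and
threshold-guided practice leaves two characteristic fingerprints in the
fitted risk curves:

* a **jump discontinuity** at a strictly honored threshold — risk drops
  abruptly where treatment switches on;
* a **counter-causal concave peak** when the threshold is only loosely
  honored — risk rises with the biomarker, crests near the decision region,
  and then *falls* as the biomarker worsens, because the sickest patients
  are the most reliably treated.

riskaudit treats these fingerprints as signal rather than as confounding to
be removed: it fits a glass-box additive risk model, then searches every
fitted component for the two shapes.

## The additive risk model

`fit_gam()` models the log-odds of a binary outcome as an additive function
of the features: `logit P(Y = 1 | x) = b0 + sum_r f_r(x_r)`, with every
`f_r` piecewise constant on a per-feature quantile bin grid. Fitting is
round-robin gradient boosting: each round visits the features in a fixed
order, and each visit fits a single best split (a depth-1 stump) on that
feature's bin grid to the current gradient of the logistic log-loss. The
round-robin schedule forces features to share explained signal, so effects
remain visible in the component they belong to; piecewise-constant
components can represent jumps exactly, which is what a threshold audit
needs. After fitting, every component is centered to training-weighted mean
zero and the intercept absorbs the shifts (the standard identifiability
convention).

Numerical choices that matter:

* **Leaf values are damped Newton steps** (per-leaf gradient sum over
  hessian sum, shrunk by the learning rate, capped at ±2 log-odds). First-
  order mean-gradient leaves converge so slowly on the log-odds scale that
  a shared shrinkage bias of ~0.1–0.2 log-odds survives hundreds of rounds
  and dominates the bootstrap band width; Newton steps remove that bias.
* **Split acceptance is gated** (`min_gain_mult`): a stump is applied only
  when its squared-error gain over the no-split fit, normalized by the
  current residual variance, exceeds `min_gain_mult * log(#candidate
  splits)`. Under no signal this statistic is the maximum of ~chi-square(1)
  variables across candidate splits, so the gate is a noise floor: without
  it, greedy stumps slowly converge the outer bins of *uninformative*
  features to their per-bin noise (worst-case ~0.15–0.2 log-odds at
  n = 20,000 with 32 bins), which both clutters the curves and feeds the
  artifact scan. The residual-variance normalization matters: early in
  training the residuals still contain the other features' unexplained
  signal, and normalizing by the hessian instead would let chance
  alignment with that signal open the gate. The default (0.1) is mild;
  the artifact-detection experiments use a strong gate (2), trading a
  small freeze bias for componentwise smoothness that stabilizes slope
  signs across bootstrap bags.
* **Binning** is by quantiles (equal-count bins), at most `max_bins` (64 by
  default), with midpoint edges when a feature has few distinct values (a
  0/1 feature gets the single edge 0.5) and empty-bin merging under heavy
  ties. Bins are half-open `[lo, hi)`; a value equal to a threshold falls
  in the right bin; outer bins are unbounded.
* **Missing values** occupy a dedicated missing bin whose value is learned
  alongside the splits — mirroring tree-based missing handling, and chosen
  here as this package's policy (how missing labs were handled in the
  motivating clinical analyses is not recorded).
* **Early stopping** monitors validation log-loss (a held-out split for
  single fits, out-of-bag rows for bags) with patience 50 by default.

`fit_bagged_gam()` fits `n_bags` (default 100) models on bootstrap
resamples. All bags share the bin grid computed on the full table, so
per-bin values are directly comparable; reported curves are bag means and
the confidence band is the empirical 95% interval across bags. The per-bag
component sets and resample indices are retained — the artifact scan uses
them.

## The discontinuity test

For an interior bin `k` of a fitted component, the locally linearized
component replaces the bin's value with the straight line through the two
neighbouring (representative point, value) anchors, evaluated at bin `k`'s
own representative point (the training mean of the feature within the
bin). The test statistic is the Bernoulli log-likelihood difference

```
T_d = loglik(fitted component) - loglik(linearized component)
```

with all other components and the intercept held fixed. `T_d > 0` means
the data prefer the jump; when the three knots are collinear the
linearized component *equals* the base and `T_d` is exactly zero. Because
the two models differ in a single bin, `T_d` reduces to a sum over the
patients in that bin — cheap enough to test every interior bin of every
component. A printed-formula variant of this statistic that mixes signs of
the outcome with logs of component values admits no consistent reading on
the log-odds scale, so the exact likelihood difference is the only form
implemented.

Interpretation of the anchors is this package's choice: anchoring at bin
representative points (rather than literally interpolating in `x` across
the window) is what makes the statistic exactly zero for locally collinear
components — a step function can never equal a sloped line pointwise — and
turns the test into a pure jump test. Outer bins have no second anchor and
are not testable; results whose three-bin window holds fewer than 20
training rows are marked low-confidence (apparent jumps in sparse regions
are often sampling artifacts).

## The non-monotonicity test

Slopes are computed across each threshold as the difference of adjacent
bin values over the distance between their representative points; slopes
with magnitude at most `slope_zero_tol` (default 1e-8) count as zero
(exact plateaus arise naturally from stump fitting). The sign sequence,
zeros removed, is segmented into runs; a changepoint is reported where two
adjacent runs of opposite sign each persist for at least `min_run`
(default 2) non-zero slopes — the noise guard that suppresses isolated
flips. A rising-to-falling flip is a *concave* peak (the counter-causal
shape, flagged); a falling-to-rising flip is a *convex* valley (a healthy
reference range — never flagged). The peak location within a flat-topped
hill is taken as the middle of the tied plateau: stump boosting quantizes
gentle hilltops, and an edge tie-break mislocates the peak by several
bins.

## Bootstrap support instead of p-values

`scan_artifacts()` runs both tests once per bootstrap bag. Discontinuity
statistics for each bag are evaluated on that bag's *out-of-bag* rows:
chance structure that a bag fitted is then scored on rows that did not
produce it, so under the null the sign of `T_d` is close to a fair coin
and the support fraction `P(T_d > 0 across bags)` is honestly calibrated.
(Evaluating on the full table instead lets the shared table noise inflate
support — the bags are resamples of the same table.) A discontinuity is
flagged when support reaches `support_level` (default 0.95) and the median
`T_d` is positive; a concave changepoint is flagged when it lands within
one bin of the same location in at least `support_level` of bags. Ranking
is by support, then by |median `T_d`|. Multiplicity across thresholds and
features is handled by this support fraction, not by p-value correction —
a documented limitation, inherited from treating the bootstrap as the
significance currency.

## The treatment-threshold simulator

The simulator composes three ingredients on a biomarker grid (domain
[0, 10], step 0.05, truncated-normal sampling density with mean 5, sd 2):

* untreated risk `p0(x) = plogis(a + b x)` (default a = −4, b = 1):
  intrinsic risk rising smoothly with the biomarker;
* treated risk `p1` from one of four benefit kinds — `flattens_risk`
  (constant level 0.15), `limits_risk` (cap 0.3), `reduces_biomarker`
  (shift 2), `constant_benefit` (log-odds offset 1.5);
* an adherence policy — `strict` (step at the threshold τ) or `loose`
  (logistic ramp of width 0.5).

Observed population risk is the mixture
`p(x) = pi(x) p1(x) + (1 - pi(x)) p0(x)`. The default decision threshold
is the round number τ = 5, deliberately *above* the optimal threshold
(where `p0` crosses above `p1`; ≈2.27 for the flattens-risk default), so
every strict scenario carries a jump at τ and every loose scenario a
concave population-risk peak. The eight benefit × policy combinations are
the scenario suite; each records which artifact class detection should
find. `excess_risk()` integrates `(p_policy - p_optimal) * density` over
the grid by trapezoid — the population cost of honoring the wrong
threshold. `sample_cohort()` realizes a scenario as patient-level rows
(biomarker, independent standard-normal nuisance features, Bernoulli
outcome); the treatment flag is generated but excluded from the exported
features, because an unobservable treatment is precisely the confounding
condition being emulated. The parametric forms are this package's concrete
instantiation of qualitative curve shapes; any parameters honoring the
per-kind contracts would do.

## Validation experiment design

The package validates itself end to end on synthetic cohorts (the
motivating clinical datasets are access-restricted). Problem sizes were
chosen once, as the study conditions:

* **Parameter recovery** (`run_parameter_recovery()`): cohorts of
  n = 20,000 from a known additive logistic model (two informative
  piecewise features, three standard-normal nuisance features), fitted
  with 200 rounds at learning rate 0.1, 20 bags, and 4 quantile bins —
  coarse bins put ≥5,000 patients behind every bin value, keeping the
  per-bin standard error (~0.03 log-odds) and hence the maximum over all
  nuisance bins well below the tolerances (informative RMSE ≤ 0.15,
  nuisance max < 0.1). The recovery target in each bin is the value that
  reproduces the bin's expected event count under the true model
  (probability-scale matching — what maximum likelihood estimates — which
  differs from the log-odds bin mean wherever a bin straddles a step).
* **Band coverage** (`run_band_coverage()`): the same benchmark at 16 bins
  and 20 bags; pooled coverage of the 95% bands over all bins is ≥80%.
  Bag standard deviations were checked against Monte-Carlo resimulations
  of the estimator and agree.
* **Artifact recovery** (`run_discontinuity_recovery()`,
  `run_nonmonotonicity_recovery()`): 50 replicates of n = 20,000
  flattens-risk cohorts (strict and loose), 32 bins, 8 bags, strong gate;
  a replicate counts as recovered when the top-ranked discontinuity (or a
  flagged concave changepoint) lies within one bin of the protocol
  threshold (or of the population-risk peak).
* **Specificity**: a U-shaped intrinsic-risk cohort (healthy mid-range,
  no treatment) must essentially never yield a flagged concave peak, and
  null cohorts (outcome independent of 20 features) must flag at most 5%
  of features. The null experiment uses 20 bags because with B bags the
  smallest nonzero chance support is 0.5^B per tested threshold, and
  ~600 thresholds are tested.

What passing these experiments does *not* show: the generator draws
independent features with an exactly additive outcome and a single
treatment rule. Real cohorts have correlated features, interactions,
time-varying and dose-dependent treatments, and informative missingness —
on such data the components remain interpretable as adjusted associations,
but artifact flags are evidence for *investigation* (the package reframes
confounding as signal), not causal proof of a misaligned protocol.

## Known limitations

* Main-effects model only; no pairwise interaction terms.
* Nominal features are fitted (per-level updates) but not audited — both
  artifact definitions require an ordered axis.
* Bootstrap support is not a familywise error rate; with very few bags the
  support fraction is too coarse to flag at high support levels.
* The excess-risk integral assumes a single crossing of untreated and
  treated risk; scenarios with multiple crossings are rejected rather than
  silently mis-summarized.
* Dose–response and longitudinal treatment models are out of scope.
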