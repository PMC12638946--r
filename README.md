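# riskaudit

Glass-box auditing of threshold artifacts in clinical risk models.

Clinical protocols turn continuous biomarkers into decisions at round-number
thresholds ("treat when creatinine exceeds 3.5 mg/dL"). Because treatment
lowers the risk of exactly the patients selected by the rule, *observed*
population risk in retrospective data blends biology with practice, and
threshold-guided care leaves two characteristic fingerprints in risk curves:

* a **jump discontinuity** at a strictly honored threshold, and
* a **counter-causal concave peak** — risk falling as the biomarker worsens —
  when the threshold is honored loosely.

riskaudit is for biostatisticians and clinical-ML researchers who want to
find these fingerprints systematically instead of de-confounding them away.
It provides:

1. **An additive logistic risk model** (`fit_gam()`, `fit_bagged_gam()`):
   the log-odds of the outcome is `b0 + sum_r f_r(x_r)` with every component
   `f_r` piecewise constant on a quantile bin grid, fitted by round-robin
   boosting of single-feature stumps with damped Newton updates and bagged
   for 95% confidence bands. Piecewise-constant components represent jumps
   exactly — the property the audit depends on.
2. **Artifact detection** (`scan_artifacts()`): every interior bin of every
   continuous component is tested for a discontinuity with the statistic
   `T_d = loglik(f_r) − loglik(f̃_r)`, where `f̃_r` is the component with the
   local jump replaced by the line through its neighbouring bins, and for
   concave non-monotonicities by changepoint detection on the signs of the
   component's slopes. Both tests are repeated across bootstrap bags
   (out-of-bag for `T_d`); the fraction of supporting bags is the
   significance currency.
3. **A treatment-threshold simulator** (`run_scenario_suite()`,
   `sample_cohort()`): composes untreated risk, one of four treatment
   benefit shapes, and a strict or loose adherence policy into observed
   population risk `p = pi*p1 + (1-pi)*p0`, quantifies the excess risk of a
   misaligned threshold, and samples patient-level cohorts in which
   treatment is a hidden confounder — closing the loop from simulated
   practice to detected artifact.

## Worked example

Simulate a cohort in which an effective treatment is given strictly above
the round number 5, although it already helps above the optimal threshold
≈2.27; fit a bagged model; audit it.

```r
library(riskaudit)

p0  <- make_untreated_risk(a = -4, b = 1)                  # intrinsic risk
p1  <- make_treated_risk(benefit_curve("flattens_risk", level = 0.15), p0)
pol <- adherence_policy("strict", threshold = 5)
sc  <- simulation_scenario(p0, p1, pol)

optimal_threshold(sc)$x_star
#> [1] 2.3
excess_risk(sc)          # population cost of honoring 5 instead of 2.3
#> [1] 0.1319805

cohort <- sample_cohort(sc, n = 20000, n_nuisance = 2, seed = 42)
model  <- fit_bagged_gam(cohort, fit_config(n_rounds = 200, max_bins = 32,
                                            n_bags = 10, seed = 7,
                                            min_gain_mult = 2))
report <- scan_artifacts(model, cohort)
head(report$discontinuities, 3)
#>     feature bin threshold        t_d bag_support low_confidence flagged
#> 1 biomarker  16  4.999282 52.6020093         1.0          FALSE    TRUE
#> 2 biomarker  17  4.999282 23.7212837         1.0          FALSE    TRUE
#> 3 biomarker  13  4.362512  0.5853464         0.9          FALSE   FALSE
```

(`min_gain_mult = 2` applies the strong split-acceptance gate, which keeps
uninformative components flat — the setting the package's own detection
experiments use.)

The top-ranked discontinuity sits at biomarker ≈ 5.0 — the simulated
protocol threshold — with positive `T_d` in all bags (`bag_support = 1`):
the likelihood prefers the jump over the locally linearized component by ~53
log-units. Excess risk of 0.132 means the round-number policy costs 13.2
extra adverse outcomes per 100 patients relative to treating at the optimal
threshold. Re-running the same scenario with a loose policy
(`adherence_policy("loose", 5, width = 0.5)`) instead yields a flagged
*concave* changepoint near the population-risk peak — the discontinuity
turns into a counter-causal non-monotonicity when adherence is soft.

A shell interface wrapping the same functions lives at
`inst/cli/riskaudit.R` (`simulate`, `fit`, `detect` subcommands; CSV and
JSON in and out).

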