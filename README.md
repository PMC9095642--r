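# glycotool

Simulation and analysis toolkit for evaluating digital lifestyle
interventions on glycemic control in type 2 diabetes.

Trials of self-managed digital tools typically randomize patients to
immediate access or a wait list, then follow everyone open-label against
registry controls on usual care. Analysing such a design needs a chain of
methods — longitudinal HbA1c trajectory classification, exposure–response
binning, weighted behaviour-change-technique (BCT) scoring, bioimpedance
body composition, exact-sex Mahalanobis matching, inverse-probability
weighting with boosted propensity scores, bootstrap mediation, and power
calculations — that glycotool implements as one tested pipeline. Because
patient-level data from such trials are rarely shareable, the package
ships a synthetic cohort generator with known ground truth (usage-class
HbA1c effects of −6.5/−4.2/−3.6 mmol/mol, a 30% obesity-related-diabetes
subgroup with an extra −2.8, 14%/4% differential dropout, a 0.15 NGSP
%/year secular drift = 1.64 mmol/mol/year in IFCC units), so every
estimator is validated by parameter recovery. It is aimed at
biostatisticians and methods researchers designing or auditing digital
diabetes interventions.

Core quantities, in the field's notation:

* Fat-free mass (Geneva single-BIA):
  `FFM = −4.104 + 0.518·h²/R + 0.231·w + 0.130·Xc [+ 4.229 if male]`
  (h in cm, R/Xc in Ω, w in kg); `FM = w − FFM`; `MM = 0.64·FFM`.
* Trajectory patterns relative to baseline: sustained decrease / sustained
  increase / oscillatory predominantly decreasing / oscillatory
  predominantly increasing, compared between groups by Fisher's exact test.
* IPW schemes: 1/p(non-dropout), 1/p(adherent) (wait group fixed at 1),
  and 1/p vs 1/(1−p) for users vs non-users, with propensities from
  gradient boosting (shrinkage 0.001, depth 3, trees tuned by
  cross-validated mean |SMD|) and HC1 sandwich standard errors.
* Two-group sample size:
  `n = ⌈(1 + 1/k)·(z₁₋α/₂ + z_pow)²·σ²/δ²⌉`.

## Worked example

```r
library(glycotool)
cfg <- cohort_config(n_participants = 370, n_registry = 2000, seed = 1)
bundle <- run_pipeline(cfg, out_dir = "run1", n_boot = 1000)
print(bundle)
#> Pipeline bundle (seed 1 )
#>   participants: 370  registry: 2000
#>   HbA1c contrasts vs matched controls:
#>               usage  estimate     ci_lo     ci_hi
#>   at_least_biweekly -5.509522 -6.656462 -4.362581
#>    at_least_monthly -4.339357 -5.162751 -3.515962
#>  at_least_bimonthly -3.629394 -4.356096 -2.902692

render_tables(bundle)$exposure
#>   themes_per_quarter n_periods mean_delta_hba1c   sem
#> 1                  0       604             0.32 0.228
#> 2                1-4       498            -0.85 0.269
#> 3                >=5       246            -1.47 0.369

print(bundle$mediation)
#> Mediation decomposition (n = 337, 1000 bootstrap draws)
#>   total           -0.0841  [-0.1030, -0.0666]
#>   direct          -0.0563  [-0.0794, -0.0326]
#>   indirect        -0.0278  [-0.0430, -0.0143]
#>   prop_mediated    0.3307  [0.1643, 0.5394]
```

The contrasts are change of HbA1c (mmol/mol) from baseline to end of
follow-up in users at each usage frequency minus matched registry
controls, with 95% CIs — the generator truths of −6.5/−4.2/−3.6 sit inside
all three intervals. The exposure table shows the within-person
quarterly dose–response: quarters with no completed themes drift slightly
upward while quarters with ≥5 themes fall by ~1.5 mmol/mol. The mediation
block decomposes the per-theme HbA1c effect into a direct part and a part
running through body-weight change (about a third here, matching the
generator's built-in split).

Design calculations are one-liners:

```r
sample_size_two_groups(delta = 2, sd = 6)                        # 142 per group
sample_size_two_groups(delta = 5, sd = 7, allocation_ratio = 2)  # 24 cases, 48 controls
empirical_power(142, 142, delta = 2, sd = 6)                     # ~0.80
```

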