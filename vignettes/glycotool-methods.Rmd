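---
title: "Methods behind glycotool: simulating and analysing a digital lifestyle trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind glycotool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotool)
```

## The study design being emulated

glycotool implements the statistical machinery of a two-phase evaluation of
a self-managed digital lifestyle tool in type 2 diabetes. In the first
phase participants are randomized 1:1 to immediate access or a 12-week wait
list; in the second, open-label phase all participants may use the tool and
are compared with registry controls on usual care, matched 1:2. The primary
outcome throughout is the change of HbA1c (IFCC units, mmol/mol). Because
the patient-level data of such a trial are not public, the package pairs
every analysis with a synthetic cohort generator whose ground truth is
known, so that each estimator can be validated by parameter recovery.

## The synthetic cohort generator

`cohort_config()` fixes the simulated conditions once:

* 370 participants, 61.9% male, age 63.3 (SD 9.7) years, BMI 31.1 (5.2)
  kg/m^2, baseline HbA1c 63.2 (10.2) mmol/mol drawn from a normal truncated
  below at the 52 mmol/mol inclusion floor (resampling until above the
  floor). Truncation raises the realised mean to the truncated-normal mean
  (about 65.8 mmol/mol); tests compare against that closed form rather than
  the untruncated location parameter.
* A 30% Mild Obesity-related Diabetes (MOD) subgroup — the obese,
  insulin-resistant cluster with preserved secretion — with an extra
  -2.8 mmol/mol response when actively using the tool.
* Randomization-phase dropout of 14% in the access arm versus 4% on the
  wait list; dropouts contribute only their baseline visit.
* Four disjoint usage classes with probabilities 0.22 / 0.31 / 0.21 / 0.26
  (biweekly, monthly, bimonthly, non-user), derived from the trial's nested
  usage groups of 59, 145 and 204 of 274 analysable participants.
* Usage-class HbA1c effects of -6.5, -4.2 and -3.6 mmol/mol at full
  exposure. The effect ramps in linearly over the first 365 days of active
  use (wait-arm use starts at week 12) and is then maintained, matching the
  sustained response the trial reports. Each total effect is split into a
  body-weight-mediated part (class-specific weight effects of -2.9 / -2.2 /
  -1.6 kg times 0.67 mmol/mol per kg) and a direct remainder, so mediation
  analyses have a known truth.
* A secular drift of 0.15 NGSP %/year applied to everyone. Trial HbA1c is
  carried in IFCC units, so the drift is converted with the increment form
  of IFCC = 10.929 x (NGSP - 2.15), i.e. 1.639 mmol/mol/year
  (`ngsp_to_ifcc_delta()`).
* Per-visit measurement noise with SD 6/sqrt(2) = 4.24 mmol/mol, chosen so
  the SD of a change between two visits is the 6 mmol/mol used in the
  trial's power calculation.

Visits are quarterly (~91 days, +/- 7 days jitter) in year 1 and
semiannual (~182 days) thereafter. Theme completions per active quarter are
negative binomial (size 5) with class means 6.5 / 3.25 / 1.6 / 0; the trial
reports only the binned period counts (114 / 228 / 311 periods with 0, 1-4
and >=5 themes), so these means are a loose calibration to those
proportions, not a fit. Bioimpedance is generated by inversion: a fixed
per-participant fat-free-mass fraction (normal around 0.65 for males, 0.55
for females, SD 0.06, clipped to [0.40, 0.80]) times current weight is
pushed through the FFM equation to solve for resistance at a drawn
reactance (normal 50, SD 8 ohm). This guarantees physiologic fat mass and
makes the measurement layer exactly invertible, which the tests exploit.

The registry pool shares the covariate distributions (so matching is
feasible), has routine-care measurements every 90-150 days over six years
from diagnosis, follows the same drift, and experiences random
medication-change events. All randomness is funnelled through the config
seed with fixed per-stage offsets, so any stage can be regenerated in
isolation; repeated runs are byte-identical.

What the generator does *not* emulate: regression to the mean from
enrolment on an elevated HbA1c, seasonal variation, informative dropout,
clustered care-provider effects, or any real behavioural feedback between
glycemia and usage. Passing recovery tests therefore show the estimators
are correct under the stated model, not that the trial's point estimates
would replicate.

## Deterministic measurements

Body composition uses the Geneva single-BIA fat-free-mass equations
(male: -4.104 + 0.518 h^2/R + 0.231 w + 0.130 Xc + 4.229; female
identical without the final constant) and the Sun total-body-water
equations, with height in cm and impedance in ohm — the units of the
source equations, which the pipeline keeps implicit. Fat mass is weight
minus FFM, and muscle mass is 0.64 x FFM (FFM less 29% extracellular
water and 7% bone mineral; the approximate percentages are fixed to exact
constants for testability). Implausible predictions (FFM >= weight) raise
errors and are never clipped, so bad inputs surface instead of biasing
downstream contrasts. IPAQ activity converts at 8.0 / 4.0 / 3.3 MET for
vigorous / moderate / walking minutes, with kcal = MET-min x weight/60.

## Trajectory patterns

`classify_pattern()` labels a series relative to its baseline (the first
in-frame measurement) with four rules applied in order, first match
winning: sustained decrease (some strictly below, none above), sustained
increase (mirror), oscillatory predominantly decreasing (majority but not
all at or below), oscillatory predominantly increasing (half or more but
not all strictly above). Ordering matters because the oscillatory
definitions overlap at the boundary; the sustained categories are defined
first. Two reading choices are made literally: "majority" is strictly more
than half, and a series with exactly half of measurements above baseline
(failing rules 1-3) is oscillatory increasing. A series whose follow-ups
all equal baseline matches no rule and is reported as unclassifiable
rather than forced into a category. Eligibility (>= 3 measurements within
a 3-year frame, baseline >= 52 mmol/mol, no medication change in-frame) is
a separate, configurable filter. Group rates of sustained improvement are
compared with the two-sided Fisher exact test.

## Exposure-response and BCT scoring

Quarterly periods are adjacent year-1 visit pairs with HbA1c at both ends;
completions count in the half-open interval (previous visit, current
visit] to avoid double counting on visit days, and periods with a missing
bounding HbA1c are dropped, never imputed. Periods are binned at 0, 1-4
and >=5 completed themes with mean and SEM of the HbA1c change per bin.

For behaviour-change-technique scoring, each theme carries 2-4 BCTs with
dominance weights. The published weight table is not reproduced here, so
weights default to normalised (sum 1 per theme) random dominance; a
user-supplied catalog overrides them. Participants completing a theme in a
period are responders if their HbA1c fell (delta < 0 strictly; delta = 0
counts as "similar or higher") and the responder/non-responder counts are
multiplied by the theme's BCT weights and accumulated. A theme completed
twice by one participant in one period counts once by default
(`count_repeats` flips this; the source leaves it unstated). The 2 x K
score table is tested by Pearson chi-square with scores treated as counts;
because the scores are weighted sums the statistic scales with the weight
normalisation, which the function flags with a warning whenever scores are
non-integer.

## Matching, weighting and inference

Matching is greedy nearest-neighbour without replacement, exact on sex,
1:2 by default, on the Mahalanobis distance over age, BMI and HbA1c using
the covariance of the eligible candidate pool per sex stratum. The
algorithm and the without-replacement choice are our own (the source does
not state them); greedy matching in seeded random participant order is
simple and reproducible. Each registry patient's index date is drawn
uniformly among admissible dates — at least two years after diagnosis with
a medication-change-free follow-up window — before matching. Balance is
reported as standardized mean differences before and after.

Propensity scores come from gradient boosting (shrinkage 0.001, depth 3),
with the tree count chosen to minimise the cross-validated mean absolute
SMD under the implied weights; missing covariates are handled by the
algorithm splitting only on observed values. Three weight schemes are
supported: inverse probability of being a non-dropout (wait group fixed at
1), of recommended use (wait group 1), and user-versus-non-user
(1/p and 1/(1-p)). Weighted contrasts use weighted least squares with an
HC1 sandwich standard error — the small-sample-corrected variant, chosen
because the analysis plan says only "robust sandwich estimator".
Unweighted endpoint contrasts use the Welch t-test (a robust default where
an "independent t-test" is stated; negligible difference at these sizes).
No multiplicity adjustment is applied anywhere; p-values are reported raw.

Mediation is the linear no-interaction decomposition: a-path
(mediator ~ exposure + moderators), b and direct paths
(outcome ~ exposure + mediator + moderators), indirect = a x b, total =
direct + indirect (an algebraic identity with the reduced-model exposure
coefficient, which tests verify to 1e-9). Moderators enter mean-centred.
Intervals are percentile bootstrap over whole subjects, 5000 draws by
default.

Sample sizes use the closed-form normal approximation
n = ceil((1 + 1/k)(z_{1-a/2} + z_{pow})^2 sd^2 / delta^2) — chosen over an
iterative t-based formula because it reproduces both of the trial's
printed designs exactly (142 per group at delta 2, SD 6; 24 cases and 48
controls at delta 5, SD 7, 1:2) — and `empirical_power()` verifies any
design by Monte-Carlo simulation of the Welch test.

## Numerical and scale choices

Probabilities from the propensity model are clipped to [1e-6, 1 - 1e-6]
before inversion. SMD uses population-form (weighted) variances. Degenerate
inputs — single-class labels, empty strata, zero pooled SD, all-zero
weights in a group — raise typed errors rather than returning NaN. Test
simulations are scaled to run comfortably on one CPU: parameter-recovery
uses 200 replicates of a 200-participant cohort (recovering the -6.5
mmol/mol biweekly effect to within 0.5), the classifier property runs on
10^5 random series, and moment convergence is checked at n = 10,000;
the full default pipeline (370 participants, 10,000 registry patients,
5000 bootstrap draws) runs in a few minutes.

## Known limitations

The BCT chi-square on weighted scores inherits the scale caveat above and
should be read as descriptive. The generator's usage classes are assigned
independently of covariates, so IPW corrections are validated for
calibration (they must not introduce bias) rather than for confounding
removal; confounded scenarios can be built by overriding the config. The
published trajectory-pattern proportions from the source registry are not
reproduction targets — they depend on private data — and only the
classifier and its test machinery are validated here.
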