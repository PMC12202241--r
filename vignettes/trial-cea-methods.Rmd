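---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## Setting and scope

trialcea implements the economic-evaluation pipeline used alongside two-arm
randomized trials: an intervention group (IG) against a comparator (CG,
e.g. a waiting list), outcomes assessed at baseline (T0) and once at
follow-up (T1, four months later), health-related quality of life measured
with the EQ-5D-5L, psychological distress with the BSI-18 Global Severity
Index (GSI, 0–72), and health-care resource use collected retrospectively
over a 6-month window at baseline and a 4-month window at follow-up.
Everything downstream — costing, regression adjustment, bootstrap
uncertainty, acceptability curves — operates on one row per participant,
so every function takes a data frame first and returns a tibble.

Because patient-level trial data of this kind are rarely shareable, the
package ships a synthetic cohort generator whose defaults state a concrete,
fixed world (below). All tests and examples run against it.

## Health effects

**QALYs.** With two assessments, "linear interpolation of the utility index
over the horizon" has a unique consistent reading: the area under the
interpolant, i.e. the trapezoid

$$\mathrm{QALY} = \frac{u_{T0}+u_{T1}}{2}\cdot\frac{h}{12},\qquad h = 4.$$

`qaly_auc()` implements exactly this; utilities pinned at the instrument
bounds (1 and −0.661) give 0.33 and −0.22 after two-decimal rounding, a
useful end-to-end check. EQ-VAS QALYs divide the 0–100 rating by 100 first.
No discounting is applied: the horizon is under a year. QALYs are computed
from *raw* per-participant utilities; covariate adjustment enters later
through the regression stage, not by pre-adjusting utilities.

**Value sets.** The EQ-5D-5L descriptive system spans $5^5 = 3125$ states.
A value set is an additive table: intercept 1 for `11111`, non-positive
decrements per dimension level, non-increasing within dimension. National
tariffs are external publications, so users supply them as CSV
(`read_value_set()`); the bundled `synthetic_value_set()` is calibrated
only so that the extreme profiles score exactly 1 and −0.661 — it is
range-faithful, not preference-faithful, and is labelled synthetic
everywhere.

**Reliable improvement.** The Jacobson–Truax reliable change index with
reference SD 7.44 and Cronbach α 0.93 gives
$1.96 \times 7.44 \times \sqrt2 \times \sqrt{0.07} = 5.4563$, rounded to
5.46. The classification uses the *rounded* threshold because that is how
the criterion is defined and reported in practice; `rci_params(rounding=)`
makes the convention overridable. The reference mean (4.66) is carried as
metadata only — the threshold needs only SD and reliability. A reduction
exactly equal to the threshold counts (inclusive ≥), deterioration never
does, and the classification is invariant to shifting both scores.

## Costs

Quantities in `ru_<window>_<category>` columns are valued by
`euro_per_unit`, inflated between price years with a CPI series
(proportional scaling, invertible). Conventions, each switchable:

* **Care time.** Categories with unit `care_hour` are valued at a
  substitute-care hourly wage rather than a market price (the assumption
  that informal care could have been replaced by formal care).
* **Medication.** Priced per pack as an ordinary category; real
  pharmaceutical databases are proprietary, so pack prices are
  configuration, not code.
* **Indirect costs.** Human-capital approach: (days absent +
  presenteeism day-equivalents $(1-w/10)\,d$) × 8 h × gross wage. The work
  module of the instrument is administered at follow-up only, so indirect
  costs enter only the follow-up window; baseline totals are category costs
  alone.
* **Perspectives.** Societal (SP) = categories + intervention + indirect.
  Payer (PP) drops indirect costs and any category flagged
  `payer = FALSE` in the unit-cost table (all categories are payer-covered
  by default, making PP = SP − indirect unless configured otherwise).
  PP ≤ SP holds row-wise by construction and is asserted in tests.
* **Missing vs zero.** A missing quantity yields a missing total — never a
  silent zero — because the primary analysis is complete-case and the two
  states must stay distinguishable. Whether a respondent's partially
  missing categories should instead be zero-filled is a data-cleaning
  decision left upstream of the package.
* **Intervention costs.** Carried per participant in the cohort
  (`intervention_cost_t1`), applied only to IG at follow-up. The
  "high intervention cost" sensitivity replaces them with a configured
  scalar (default €1101 ≈ 1.5 × the €734 default mean) rather than
  re-deriving a wage-based revaluation from pay tables.
* **Winsorization.** `winsorize_totals()` caps values above the empirical
  percentile (95th by default) at the linear-interpolation (R type 7)
  quantile. With an interpolated cap the operation is exactly idempotent
  only when $p\,(n-1)$ is an integer (the cap then is an order statistic);
  otherwise a second pass can move the cap by a sliver. Tests pin the
  convention and assert idempotence where it holds exactly.

## Regression: seemingly unrelated cost and effect equations

Costs and effects from the same participant are correlated; modelling them
jointly carries that correlation into the uncertainty of their ratio. The
two linear equations are

* cost: follow-up total ~ arm + gender identity + age + baseline-window
  total;
* effect: QALY (or EQ-VAS QALY, or the reliable-improvement indicator) ~
  arm + gender identity + age + baseline utility index + baseline GSI,

estimated by Zellner feasible GLS (`fit_sur()`): equation-wise OLS,
2×2 residual covariance, then GLS on the stacked system. One-step FGLS is
the default, matching common practice; `iterate = TRUE` iterates to
convergence. With identical regressors in both equations FGLS reduces
exactly to OLS — the classical result the correctness tests lean on. The
stacked normal equations mix euro² and QALY² scales (condition numbers near
machine precision with heavy cost tails), so the solver applies Jacobi
equilibration before inverting; this is purely numerical and changes no
estimate.

Choices worth stating:

* **Linear probability model.** The reliable-improvement equation enters
  the linear system as an LPM because SUR requires jointly linear
  equations and the quantity reported is an adjusted percentage-point
  difference, which is precisely the LPM arm coefficient. Known caveats
  (predictions outside [0,1] possible in extrapolation, heteroskedastic
  errors) are mitigated by robust SEs and bootstrap-based inference; tests
  check adjusted proportions stay in [0,1] under the default world.
* **Adjusted means by g-computation.** Every participant is predicted
  under arm = IG and arm = CG and the counterfactual columns averaged.
  For linear models without interactions this equals prediction at
  covariate means, and the difference equals the arm coefficient — an
  identity asserted at run time, so the two conventions cannot drift.
* **Reference categories.** Gender identity is coded with trans-masculine
  as reference; a reference-swap test verifies that nothing reported
  depends on the choice. In gender-identity subgroup analyses the
  covariate is constant and is dropped from both equations.
* **Standard errors.** Heteroskedasticity-robust (sandwich) model SEs are
  reported, but interval estimation and all cost-effectiveness outputs
  rest on the bootstrap.
* **Unadjusted comparisons** use the one-way linear-model F test, which on
  two groups equals the squared equal-variance t statistic (asserted to
  1e-10). Groups that differ with zero within-group variance return
  F = ∞, p = 0 rather than an unstable `lm` fit.

## Bootstrap and BCa intervals

`bootstrap_contrasts()` resamples *participants* with replacement — the
participant is the exchangeable unit, keeping each person's costs and
effects paired — refits the SUR per replicate (B = 1000 by default) and
records the two arm coefficients. Resampling is unstratified by default;
`stratify_by_arm = TRUE` preserves arm sizes for users who prefer the
conditional reading. Replicates whose refit fails (e.g. collinear
resamples) are redrawn up to 10 × B attempts and the count is reported,
because silently dropping them would bias the acceptability-curve
denominator. Draw sets are exactly reproducible from (data, B, seed),
ordering included, and serialize to CSV + JSON sidecar.

`bca_interval()` follows the textbook BCa construction: bias correction
$z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$, acceleration from
the jackknife skewness of leave-one-out estimates
($a = \sum (\bar\theta_{(\cdot)}-\theta_{(i)})^3 / (6[\sum(\bar\theta_{(\cdot)}-\theta_{(i)})^2]^{3/2})$),
endpoints at the adjusted percentile levels using type-7 quantiles. With
$z_0 = a = 0$ it reduces exactly to the percentile interval; an all-equal
draw set returns a flagged degenerate interval; a point estimate outside
the draw range clamps $z_0$ with a warning rather than returning ±∞.
An independently coded transcription of the same construction serves as
the test oracle.

## ICER, plane and acceptability curves

`icer()` reports $\Delta C/\Delta E$ with its cost-effectiveness-plane
quadrant (NE costlier/more effective; SE dominant; NW dominated; SW
cheaper/less effective). Tie rule: zero incremental effect joins the
less-effective half-plane and zero incremental cost the costlier one —
probability-zero events for continuous draws, fixed only so the partition
is deterministic. A zero-effect denominator yields a flagged undefined
ratio, never a division error.

`ceac()` offers two definitions and emits which one was used:

* **net_benefit** (default): share of draws with strictly positive net
  monetary benefit $\lambda\,\Delta E - \Delta C$. Quadrant-safe; ties
  count as not cost-effective. Non-decreasing in λ whenever all effect
  draws are positive (asserted on sorted grids).
* **icer_below_wtp**: the verbal "share of bootstrapped ICERs below the
  threshold", completed by the quadrant rule that keeps it sign-consistent
  with net benefit: SE always counts, NW never, and in SW — where a lower
  ICER is *worse* — a draw counts when its ICER exceeds λ.

The definitions coincide exactly on NE-only draw clouds (tested by brute
force) and diverge outside; net benefit is the default because it is the
method the acceptability-curve literature defines and it needs no special
cases. Default willingness-to-pay grids are €0–300,000 per QALY (step
1,000) and €0–30,000 per reliable improvement (step 100), covering the
commonly discussed €50,000/€150,000 and €5,000/€15,000 thresholds.

## The synthetic world

`generator_config()` defaults state one fixed scenario; they were chosen
once, against the published summary statistics of a trial of this design,
and are not tuned afterwards:

* arms of 88 (IG) and 80 (CG); age ≈ N(26.8, 10²) truncated at 18; gender
  identity trans-masculine/trans-feminine/nonbinary with probabilities
  0.434/0.339/0.227;
* baseline utilities N(0.83, 0.19²) in IG and N(0.87, 0.19²) in CG,
  clipped to [−0.661, 1], with follow-up changes +0.02/−0.03; note the
  clipping shrinks *observed* means a couple of hundredths below the
  configured locations — the configured values are the generating means,
  not the realized ones;
* EQ-VAS baselines 68.52/72.73 (SD 21), changes +1.55/−2.28;
* GSI change as an explicit mixture: with probability 0.23 (IG) / 0.09
  (CG) a participant is a responder whose reduction is the 5.46 threshold
  plus a half-normal margin (responders draw baselines with headroom ≥ 10);
  non-responders change by a normal truncated strictly below the
  threshold. The mixture makes the classification margins equal the
  configured probabilities exactly, so parameter-recovery tests have a
  known truth;
* per-category costs as zero-inflated lognormals calibrated so the
  6-month baseline societal total averages ≈ €3,500 with SD ≈ €7,000
  (SE ≈ €780 at n = 84) — heavy right skew dominated by inpatient days and
  care hours; follow-up means scale by the window ratio (4/6) times a
  0.40 use-restraint factor, reproducing a comparator-arm follow-up total
  near €1,500;
* the intervention arm's follow-up increment: €656 expected extra
  counseling use (gamma, shape 4) plus a fixed intervention cost
  N(734, 94²) floored at 0 — SD 94 ≈ 10·√88, so the arm-mean SE at the
  default size is €10; total configured cost effect €1,390;
* a shared latent Gaussian factor with loading 0.2 ties utilities and
  category costs together; no published joint distribution exists, so the
  value is a declared modelling choice;
* work data: 35% any absenteeism (lognormal days), ≈35 days at work,
  performance ≈ N(9.5, 0.8) on 0–10 — indirect costs ≈ €580 per follow-up
  window with no arm effect;
* one substream per participant derived from the master seed, so cohorts
  are reproducible and early participants are unchanged when an arm grows.

What the generator does **not** emulate: item-level BSI-18 responses,
EQ-5D dimension transitions over time (profile mode draws levels from a
severity latent, qualitatively only), real national CPI series or unit
costs (both bundled tables are synthetic and labelled so), informative
missingness (injection is MCAR), and any correlation between work
variables and clinical outcomes. A green test therefore establishes that
the *pipeline arithmetic and inference machinery* behave as specified under
a realistic-shaped world — not that any clinical conclusion transfers.

## Populations, missingness and attrition

The cohort carries explicit analysis flags (intention-to-treat, analysis
population, per-protocol) so populations are selectable without re-deriving
exclusions. Estimation is complete-case *per model*: only rows missing a
variable of the current specification are dropped, so different effect
measures legitimately use different n — mirroring how trial tables show a
varying case base rather than one global listwise deletion. The
`complete_case` population makes that filtering explicit and is verified
to equal the per-model behaviour. MCAR masking at configurable rates is
available (`inject_missingness()`) for robustness exercises; multiple
imputation is deliberately out of scope.

## Known limitations

* The LPM can extrapolate outside [0,1] for covariate values far from the
  data; a GLM effect equation is out of scope by design.
* BCa coverage inherits the known small-sample behaviour of the bootstrap
  under heavy-tailed costs; at the default trial size the 95% interval for
  the cost contrast covers the configured truth ≈ 93% of the time in the
  package's own 500-trial simulation, and materially smaller trials can
  dip below 0.90.
* Winsorization's exact-idempotence caveat above.
* The generator's utility clipping means configured and observed baseline
  means differ slightly; calibrate against observed summaries if that
  distinction matters for a power exercise.
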