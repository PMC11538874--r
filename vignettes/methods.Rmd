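---
title: "Methods: trial-based economic evaluation of a digital stress-management intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based economic evaluation of a digital stress-management intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressecon)
```

# The evaluation problem

`stressecon` analyses a two-arm randomized trial of a guided,
internet-based stress-management intervention for employees against a
waitlist control, over a 6-month time horizon, from two perspectives:

* **Societal**: all resource use counts — health care, patient and
  family costs, productivity losses, and the intervention itself. The
  question is cost-effectiveness (cost per symptom-free employee) and
  cost-utility (cost per quality-adjusted life year, QALY).
* **Employer**: only the intervention price and productivity losses
  count. The question is financial: net benefit, return on investment
  (ROI), benefit-cost ratio, and the probability of a positive return.

Per participant the data comprise arm assignment, demographics, gross
daily wage, Perceived Stress Scale (PSS-10, 0–40) scores at baseline
and 6 months, health-state utilities in $[0,1]$ at baseline and 6
months (primary instrument plus an optional alternative), and
TiC-P-style resource-use counts over two 3-month recall windows
(plus a pre-baseline window used as a cost covariate).

# Costing

Cumulative 6-month costs sum the two follow-up recall windows,
valued with `unit_cost_table()`:

| Component | Method | Default |
|---|---|---|
| GP visit | unit cost | €20.92 |
| Psychiatrist session | unit cost | €46.55 |
| Psychotherapist session | unit cost | €81.44 |
| Allied health contact | unit cost | €17.08 |
| Inpatient psychiatric day | unit cost | €335.52 |
| Inpatient psychosomatic day | unit cost | €306.41 |
| Travel | per km | €0.30 |
| Medication, OTC, out-of-pocket | amounts pass through | — |
| Unpaid work, informal care, domestic help | proxy good method, per hour | €18.33 |
| Absenteeism | human capital method: days × gross daily wage | — |
| Presenteeism | Osterhaus method: impaired days × inefficiency × wage | — |
| Intervention | fixed price per intervention participant | €99 |

Amounts are indexed to the reference year with a multiplicative
factor (default 1.04) and converted to pounds sterling with a
purchasing-power-parity rate (default £0.85/€), reproducing the
worked conversion €99 → £84 (`index_and_convert()` with
`already_indexed = TRUE`, since the price is already in reference-year
euros). The societal total is the sum of all categories; the employer
total is intervention + absenteeism + presenteeism.

# Outcomes

* **Symptom-free status**: PSS-10 at follow-up at or below the pooled
  baseline mean minus two pooled baseline standard deviations
  (`symptom_free_threshold()`; 22.65 − 2 × 5.63 = 11.39 for the
  emulated trial). The boundary is inclusive — "at least 2 SD below"
  is read as ≤ — which `is_symptom_free(inclusive =)` makes
  explicit.
* **QALYs**: area under the utility curve between baseline and 6
  months by the trapezoid rule (`qaly_auc()`), so half a year of
  perfect health is 0.5 QALYs and printed group means (0.321, 0.306)
  give the incremental 0.015.

# Missing data

Follow-up fields (follow-up PSS, utilities, and the whole second
recall window) are imputed with an in-package implementation of
multiple imputation by chained equations with predictive mean
matching (`mice_pmm()`):

1. Missing cells start from random draws of observed values.
2. For a fixed number of sweeps, each incomplete variable is
   regressed on the baseline predictors (demographics, wage, baseline
   PSS and utility, pre-baseline costs), the other core follow-up
   scores, and its own first-window counterpart; regression
   parameters are drawn from their Bayesian posterior; each missing
   cell receives the *observed* value of a donor drawn uniformly from
   the k = 5 closest predicted means.
3. The procedure runs separately per arm, so no information crosses
   arms and every imputed value is an observed within-arm donor value
   (this is a tested invariant).

Defaults are m = 30 imputations and 10 sweeps; the examples and tests
use smaller values for speed. Pooling uses Rubin's rules
(`rubin_pool()`): total variance = within + (1 + 1/m) × between, with
Barnard–Rubin degrees of freedom when a finite complete-data df is
supplied. PMM is used precisely because cost components are
right-skewed and zero-inflated; regression imputation would produce
negative or un-skewed values.

# Estimation

For each completed dataset an `analysis_frame()` joins costs,
outcomes and baseline covariates. Incremental costs and effects come
from a two-equation seemingly-unrelated-regressions (SURE) system
(`fit_sure()`):

* cost equation: total cost ~ treatment + pre-baseline total cost;
* effect equation: QALYs ~ treatment + baseline utility, or
  symptom-free status as a linear probability ~ treatment + baseline
  PSS.

The system is estimated by two-step feasible generalized least
squares with correlated residuals. Two numerical conventions matter:

* With identical regressor sets GLS degenerates to per-equation OLS;
  the implementation also *detects* degenerate residual covariance
  (zero-variance equations, perfectly correlated residuals — both
  arise in small bootstrap resamples) and falls back to per-equation
  OLS, which is the correct limit.
* Bootstrap resampling is stratified by arm (the design fixes arm
  sizes), with B replicates allocated evenly across the m imputed
  datasets into one pooled replicate cloud of (ΔC, ΔE) pairs
  (`bootstrap_cea()`). The point estimate is the Rubin-pooled pair.

From the cloud: BCa confidence intervals (`bca_ci()`; bias correction
from the replicate distribution, acceleration from a jackknife on the
first completed dataset; quantile type 7), the ICER with its
dominance taxonomy (`icer()`), the cost-effectiveness plane quadrant
distribution (`ce_plane_distribution()`; southeast = more effective
and cost-saving = dominant), and the cost-effectiveness acceptability
curve (`ceac()`): the fraction of pairs with positive net benefit
λ·ΔE − ΔC at each willingness-to-pay λ. A pooled logistic regression
(`logistic_effect()`) reports the treatment odds ratio for
symptom-free status, and `nbrf_moderation()` implements the
net-benefit regression framework for subgroup probing (treatment ×
moderator interactions on per-participant net benefit, with
unadjusted p-values and a clearly-labelled Bonferroni column).

# Employer cost-benefit analysis

The employer's benefit is the adjusted control-minus-intervention
difference in productivity costs: the sign-flipped treatment
coefficient of `lm(productivity_cost ~ treat +
baseline_productivity_cost)`, Rubin-pooled (`employer_benefit()`).
With fixed intervention costs C and benefits B: net benefit = B − C,
ROI = (B − C)/C × 100, ratio = B/C (worked example: B = 175, C = 99
gives 76, 77%, 1.77). `bootstrap_cba()` bootstraps the benefit the
same stratified way and reports the probability of a positive return
as the fraction of replicates with positive net benefit — identical
to the fraction with positive ROI, a tested identity.

# Sensitivity analyses

`default_scenarios()` declares the main analysis plus three re-runs
(`run_scenario()`, same seed throughout):

1. **Winsorized costs**: per-participant cost totals capped at the
   95th percentile within each completed dataset. The percentile is
   the inverse-ECDF order statistic (quantile type 1), chosen over
   interpolating conventions because only an order-statistic cap
   makes winsorizing exactly idempotent (re-interpolating on capped
   data lowers the cap again); idempotence and sort-equivariance are
   tested invariants.
2. **Intervention repriced at €299**: shifts every
   intervention-participant cost by exactly +€200, so the employer
   net benefit moves by exactly −€200 and effect estimates are
   unchanged (up to last-bit FGLS noise) — both tested.
3. **Alternative utility instrument** (EQ-5D-style column), societal
   perspective only, since the employer analysis uses no utilities.

# The synthetic trial generator

No participant-level data ship with the package; `generate_trial()`
emulates the trial the analysis assumes, with every "true" quantity
fixed by construction:

* n = 198 per arm; baseline PSS normal (mean 22.65, SD 5.63,
  truncated to 0–40); follow-up PSS correlated with baseline with a
  standardized treatment effect d = 0.65 (configurable).
* Utilities: truncated normals in $[0,1]$ (baseline mean 0.60, SD
  0.12) with a control drift and an intervention gain calibrated so
  the true incremental QALY is exactly 0.015 by the trapezoid rule;
  an alternative-instrument column has a smaller gain.
* Cost components: counts are negative binomial (size 0.6); euro
  amounts are zero-inflated gamma (30% zeros, shape 1.2);
  inefficiency scores are Beta(2, 3); wages are gamma with mean €150.
  Per-category window means are calibrated so the true societal
  incremental cost is exactly −€38, the employer incremental −€76,
  and the true adjusted employer benefit €175 — the generator's truth
  parameters are returned with the dataset and frozen in tests.
* Dropout: `apply_missingness()` blanks all follow-up fields jointly
  (monotone dropout) for ~21% of participants via a logistic
  missing-at-random model whose intercept is calibrated by root
  finding to hit the target rate. The default dependence (+0.25 SD
  per baseline-PSS SD, −0.25 per baseline-utility SD) makes complete
  cases unrepresentative — the imputation tests verify the MICE
  pipeline removes that bias — and setting the coefficients to zero
  gives MCAR.

**Scope and limits.** The generator reproduces the *structure* the
estimators rely on (skewness, zero-inflation, baseline-follow-up
correlation, MAR dropout, known increments); it does not model
seasonality, within-window correlation between cost categories
beyond their shared arm means, or item-level instrument scoring
(utilities are consumed as numbers).

# Determinism and problem sizes

Every stochastic step takes a seed; `run_pipeline()` derives
independent sub-seeds from one master seed (multiplicative offsets
modulo 2³¹ − 1), so a whole run is reproducible bit for bit, and the
identity scenario reproduces the main analysis exactly. Defaults
(m = 30, B = 2500, sweeps = 10) match common practice for a trial of
this size; tests and examples use reduced sizes (m = 2–5, B a few
hundred) chosen so the full suite runs in minutes — these are the
package's own choices and can be raised freely.

# Open design decisions

Points the analysis conventions leave open, and the choices made:

* Winsorizing is applied to per-participant *totals* per perspective,
  after imputation, within each completed dataset (a per-category
  variant would also be defensible).
* The symptom-free boundary is inclusive (≤ threshold).
* The intervention price is treated as already indexed to the
  reference year (no second indexing before PPP conversion).
* The acceleration constant of the BCa interval is computed on the
  first completed dataset only (it is stable across imputations).
* The bootstrap pools one replicate cloud across imputations rather
  than nesting a full bootstrap within each imputation.

```{r example, eval = FALSE}
# end-to-end run, written to disk
bundle <- run_pipeline(pipeline_config(seed = 1, out_dir = "results"))
```
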