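---
title: "Prospective matching to guide enrollment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospective matching to guide enrollment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prospmatch)
```

## The design

When a care model is rolled out system-wide and patients transfer into it by
joint patient–provider decision, randomization is off the table, but a
rigorous comparison is still possible if enrollment itself is guided by
matching. The design this package implements proceeds in near real time:

1. a rolling administrative data pull identifies patients who have just
   transferred to the treatment model (treated-eligible) and patients who
   remain in usual care (control-eligible);
2. for each treated-eligible patient a *pool* of controls is built by
   coarsened exact matching plus a minimum-distance ranking;
3. once the treated patient enrolls, their pooled candidates are contacted in
   distance-priority tiers until one enrolls, forming a dyad;
4. covariate balance of the enrolled dyads is audited with standardized mean
   differences (SMDs);
5. the dyad target itself comes from a simulation-based power calculation for
   zero-inflated count outcomes.

Everything here is exercisable on synthetic cohorts, so a study team can
rehearse eligibility rules, matching criteria, recruitment logistics and
sample size before touching real data.

## The synthetic cohort generator

`generate_cohort()` draws a multi-facility population whose marginals mimic
an older, predominantly male and white veteran primary-care population: age
~ Normal(80, 7²) floored at 18; CAN score (a 0–99 hospitalization/mortality
risk percentile) ~ Normal(50, 30²) rounded and clamped; JFI (a 0–13 frailty
index) ~ Normal(4, 2²) rounded and clamped; ~1.8% female, ~83% white, 28%
advance directive, 3.3% dementia; prior-year hospitalizations ~
Poisson(0.12). CAN and JFI share a latent correlation of 0.3 — the joint
distribution of these scores is not documented anywhere we know of, so this
is an explicit plausibility choice (a config knob, `can_jfi_correlation`).

Transfer to the treatment model follows a logistic model on the
*standardized* observed covariates,

```
logit P(transfer) = b0 + b_age z_age + b_can z_can + b_jfi z_jfi
                    + b_dem dementia + b_hosp z_hosp + b_u U,
```

with default weights (0.3, 0.4, 0.4, 0.7, 0.3) and intercept −3.0, giving a
transfer rate near 5% and, crucially, *confounding by observables*: the
transferred arm is older, frailer and higher-risk before matching. The
`unobserved` term `U` (default weight 0) injects residual confounding on
demand; by default selection is purely on observables, which is exactly the
regime in which matching on observables is a valid identification strategy.

Each patient receives at least two visits per one-year window (Poisson
excess around `visit_intensity` = 4/year), with exposure-period visits in
the treatment clinic for transferred patients and the usual clinic
otherwise. Day 0 is the start of the exposure period; windows are half-open
integer-day intervals `[-365, 0)` and `[0, 365)`, a convention chosen so
that no visit can be double-counted and boundary behavior is testable.

**Default scale.** The default configuration (4 facilities × 3,500 patients,
~5% transfer) was chosen so the *relative* geometry of the design matches a
fielded study of this kind: a treatment model serving a small fraction of a
large usual-care population, yielding match pools with median size on the
order of 100–130 candidates, a small percentage of treated patients lacking
the 5-candidate minimum, and a reachable target of 275 dyads. These are the
problem sizes the test-suite properties and the acceptance computations run
at.

What the generator does *not* emulate: real administrative-data artifacts
(coding churn, duplicate records, facility transfers mid-year), seasonal
visit patterns, time-varying covariates, informative missingness, or
survey-collected covariates. Passing tests therefore demonstrate the
*internal* coherence of the design machinery — eligibility logic, pool
construction, recruitment dynamics, balance arithmetic — not robustness to
real-data messiness.

## Eligibility

A patient is treated-eligible with ≥2 usual-clinic visits and no
treatment-clinic visits in the pre-exposure year **and** ≥2 treatment-clinic
visits and no usual-clinic visits in the exposure year; control-eligible
with ≥2 usual-clinic and no treatment-clinic visits in *both* years.
Hospice/palliative/institutionalized flags disqualify at classification
time (they are population requirements, not recruitment-stage attrition).
`rolling_pull()` re-runs classification using only visits observed before
each pull day and emits each patient at the first pull at which they
qualify; "quarterly" is operationalized as every 91 days (calendar quarters
have no meaning on the synthetic timeline). A patient classified as a
control at an early pull is never re-emitted; whether a real pull system
would re-classify such a patient if they later transferred is not
well-defined in the field, and with the default generator the situation
cannot arise (non-transferred patients never visit the treatment clinic).

`filter_facilities()` retains facilities with at least
`min_facility_treatment_visits` (default 500) treatment-clinic visits in the
exposure year, abstracting the volume criterion used to select participating
facilities.

## Matching

**Coarsened exact criteria.** Facility, race, sex, advance directive,
dementia, and any-hospitalization must agree exactly; "age within 5 years"
is implemented as a symmetric caliper |Δage| ≤ 5. A binned variant
(`age_bins = TRUE`) is provided for sensitivity analysis, but the caliper is
the default because "within 5 years" reads as pairwise proximity and binning
creates boundary artifacts (an 80-year-old matched to 84 but not 79).

**Distance.** Candidates are ranked by the Mahalanobis distance on
standardized age, hospitalization count, CAN and JFI. Standardization uses
the control-eligible population at the current pull (controls vastly
outnumber treated patients, so they dominate any pooled estimate; the
reference population is a documented choice, not a fielded fact). The
default covariance is diagonal — i.e., Euclidean distance on standardized
variables — because standardization-then-distance is the documented
procedure and no off-diagonal covariance is documented; `distance_mode =
"full"` switches to the full covariance of the standardized controls.
Neither mode is asserted to be what any particular fielded study used.

**Tiers.** Priority tiers band the distance: `< 0.1`, `< 0.25`, `< 0.5`,
then 1.0, 2.0, ∞. The first three thresholds are the documented ladder; the
continuation is a geometric-flavored default (configurable) since the
fielded ladder beyond 0.5 is described only as "and so on". Bands are
half-open (`[lo, hi)`), so a distance of exactly 0.1 falls in tier 2.

**Determinism.** Distance ties are broken lexicographically by control id,
so identical inputs always produce byte-identical pools. Pools are rebuilt
at each pull (the standardizer refits on the accumulated controls);
`min_pool_size = 5` reflects an expected 20% telephone enrollment rate —
five candidates per expected enrollee. A control may sit in many pools
simultaneously; uniqueness is enforced at enrollment, not pool construction.

## Recruitment

Time is discretized to weeks because the protocol is specified in weeks
(2-week escalation, 5-week window); day-level contact timing is not
documented, so reported "days between enrollments" are 7 × week-lag. An
optional within-week jitter was considered and left out: it adds a free
parameter without changing any decision the simulator informs.

Each treated patient enrolls at their pull's opening week (probability
`p_enroll_treated`, default 1). While their window is open, up to
`contacts_per_week` (default 3 — a guess at realistic interviewer capacity,
flagged as such) not-yet-attempted candidates in the open tiers are
contacted per week in (tier, distance, id) order; tier k opens (k−1) ×
`escalation_interval` weeks after the treated enrollment. Each contact
passes a record-review gate (`confirm_eligible_prob`, default 1 — letters
and medical-record review are collapsed into this single attrition
probability, with no separate delay) and enrolls with `p_enroll_control`
(default 0.20). The first enrollment forms the dyad; enrolled controls are
removed from every pool immediately; the simulation stops at `target_dyads`
(default 275). A treated patient whose window closes unmatched stays in the
study unmatched. A treated patient's pool is frozen at their enrollment
pull; whether a fielded system would re-open escalation when better
candidates arrive at a later pull is unknowable, and freezing is the
reproducible choice.

Note one structural consequence: with a 5-week window and 2-week
escalation, only the first three tiers are ever contactable for a given
treated patient. That is the faithful reading of the protocol as stated;
candidates in lower tiers matter only through configurations with longer
windows or faster escalation.

## Balance

`smd_continuous()` uses the unweighted two-group pooled SD,
`(m2 − m1)/sqrt((s1² + s2²)/2)`; `smd_binary()` the analogous
proportion form. Group 1 is the treated arm, so a covariate *higher among
treated* patients has a *negative* SMD. This specific form was retained
because it reproduces, from the printed summary statistics, the published
SMD values of the age/CAN/JFI rows of the motivating study's baseline table;
a paired (dyad-adjusted) SMD can be added by analyzing dyad differences but
is deliberately not the default. Summaries are pairwise-complete per
covariate with per-group missing counts and no imputation. Exact-matched
covariates are guaranteed SMD = 0 in any dyad set the pipeline produces —
each dyad shares the key — and the test suite asserts this exactly, not to a
tolerance. Baseline hypothesis tests are deliberately absent: SMDs are used
precisely because they are insensitive to sample size.

## Power

The sample-size engine simulates two-arm trials of `n_dyads` patients per
arm with zero-inflated count outcomes ("days not at home" over the outcome
interval): with probability π an outcome is a structural zero; otherwise it
is Poisson (ZIP) or negative-binomial (ZINB). The non-zero-component rate is
solved so the *marginal* mean hits the arm target (λ = mean/(1 − π)), since
the planning quantities are stated as patient averages (5.5 control vs 4.0
treated). Facility clustering enters as a shared log-normal frailty
`u ~ N(−σ²/2, σ²)` (so `E[e^u] = 1`), with σ² solved by `uniroot` so the
within-facility intra-class correlation of the outcome equals `icc`.

Four planning constants are *reconstruction defaults*, clearly not fielded
facts: π = 0.3 in both arms, 57 facilities, ICC = 0.05, and the analysis
model. All are config knobs. The documented ZINB scenario — "variance up to
12 times larger" — is interpreted as the ratio of the ZINB to the ZIP
marginal variance at the same mean, which yields the closed form
`theta = λ/((ratio − 1)(1 + πλ))` implemented in
`calibrate_nb_dispersion()`; a reading of "12 × the mean" can be obtained by
passing `nb_dispersion` directly.

Each replicate is analyzed by an in-package maximum-likelihood zero-inflated
regression (`fit_zi_count()`): log-link rate model with a treatment
indicator, constant zero-inflation logit, BFGS optimization with
moment-based starts, observed-information variance. With clustering, the
treatment test uses a CR1-type cluster-robust sandwich (per-facility score
sums, G/(G−1) small-sample factor) against a t reference with G − 1 degrees
of freedom — the standard small-G correction. This fitter exists in-package
because no installed library provides cluster-robust variances for
zero-inflated models; its point estimates, likelihood and model-based
standard errors are cross-checked against `glmmTMB` in the test suite.
Replicates whose fit fails are excluded and counted, with a hard error above
10% failures — excluding (rather than counting as non-rejections) avoids
biasing power downward by fragile fits, at the cost of a small optimism if
failures correlate with effect size; at the default scale failures are
essentially absent.

Type-I calibration is part of the acceptance checks: at equal means the
rejection rate must sit within Monte-Carlo tolerance of α. `power_curve()`
evaluates a grid of dyad counts under common random numbers (one maximal
trial per replicate, analyzed on nested subsets) so the curve is monotone up
to fit noise.

**Problem sizes.** The suite runs the power acceptance check at the planning
scale itself (275 dyads × 1000 replicates, plus 2000 null replicates);
moment checks use 10⁵ draws; the end-to-end pipeline runs on the default
14,000-patient cohort. These sizes were chosen as the smallest at which the
quantities being checked are statistically stable at the stated tolerances.

## Known limitations

* Selection into treatment is purely on observables by default; the
  `unobserved` selection weight exists to study violations, but no
  sensitivity-analysis machinery (e.g., E-values) is included.
* The recruitment simulator abstracts letters, record review and consent
  into two probabilities and has no notion of calendar seasonality.
* The balance module's paired structure is ignored by the default SMD (the
  unpaired form is what published baseline tables use); dyad-level analyses
  of outcomes are out of scope entirely.
* The ZINB power scenario depends on reconstruction defaults (π, ICC,
  dispersion); it is an exploration surface, not a reproduction of any
  specific fielded number.
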