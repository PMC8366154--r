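# prospmatch

Design engine for **prospective matching to guide enrollment** — the study
design in which patients who transfer into a new care model are identified
from rolling administrative data pulls, matched *before recruitment* to pools
of similar usual-care patients, and each enrolled treated patient's matched
controls are then contacted in priority order until a dyad is formed. The
design creates a concurrent, covariate-balanced comparison group for
evaluating non-randomized programs while still allowing collection of
patient-reported outcomes.

The package is for biostatisticians and epidemiologists planning such a
study: it lets you rehearse every design decision — eligibility rules,
matching criteria, recruitment windows, sample size — on synthetic cohorts
with realistic confounding before any real patient is contacted.

## What it implements

* **Synthetic cohorts** (`generate_cohort()`): multi-facility populations of
  older primary-care patients in which transfer to the treatment model is
  driven by observed covariates (age, CAN score, JFI score, dementia, prior
  hospitalizations), so unmatched arms are imbalanced by construction.
* **Eligibility** (`classify_cohort()`, `rolling_pull()`,
  `filter_facilities()`): visit-count rules over half-open one-year
  pre-exposure/exposure windows, applied through rolling quarterly data
  pulls, plus a facility volume filter.
* **Matching** (`build_pools()`): coarsened exact matching on facility, race,
  sex, advance directive, dementia and any-hospitalization, an age caliper of
  ±5 years, and a minimum-distance ranking of candidates using the
  Mahalanobis distance on standardized age, hospitalization count, CAN and
  JFI (`d(x, y) = sqrt((x - y)' S⁻¹ (x - y))`, diagonal `S` by default).
  Candidates are banded into priority tiers (`d < 0.1`, `< 0.25`, `< 0.5`,
  ...), and treated patients with fewer than 5 candidates are excluded.
* **Recruitment** (`simulate_recruitment()`): weekly discrete-event
  simulation — tier-by-tier contact at a 20% expected enrollment rate,
  escalation every 2 weeks, a 5-week window per treated patient, global
  uniqueness of enrolled controls, stop at the dyad target.
* **Balance** (`balance_table()`, `smd_continuous()`, `smd_binary()`):
  standardized mean differences, `SMD = (m₂ − m₁) / sqrt((s₁² + s₂²)/2)`,
  with the conventional |SMD| < 0.2 adequacy threshold.
* **Power** (`estimate_power()`): Monte-Carlo sample-size simulation for
  zero-inflated Poisson / negative-binomial "days not at home" outcomes with
  facility clustering, analyzed by an in-package zero-inflated count
  regression with a cluster-robust Wald test.

`run_full_study()` chains generate → filter → classify → match → recruit →
balance and emits all artifacts (CSV/JSONL/JSON). A thin command-line
front end lives at `inst/cli/prospmatch`.

## Worked example

```r
library(prospmatch)

smd_continuous(80.8, 6.9, 79.4, 7.0)
#> [1] -0.2014336        # age imbalance of -0.20 SD (group 2 younger)

st <- run_full_study(seed = 7)
st
#> Full-study run: 14000 patients, 4/4 facilities retained
#>   eligible: 849 treated, 12313 control
#>   pools: median size 105 (range 0-855), 72 lacking minimum
#>   dyads formed: 275 (502 treated unmatched)

recruitment_summary(st$recruitment)
#> Dyads: 275 (35% of 777 enrolled treated patients matched)
#> Tier of enrollment:
#>   tier 1: 9.5%
#>   tier 2: 38.5%
#>   tier 3: 52.0%
#> Median days between enrollments: 28
```

The run reaches its 275-dyad target; 72 of 849 treated-eligible patients
(8.5%) lacked the 5-candidate minimum and were never recruited. Matching
removes the generator's confounding: before matching the treated arm is
older, frailer and higher-risk (age SMD −0.30, JFI −0.54, CAN −0.41), while
across the enrolled dyads every exact-matched covariate has SMD exactly 0
and the distance variables are essentially exact:

```r
post <- as.data.frame(st$balance_post)
post[post$covariate %in% c("age", "can_score", "jfi_score", "race:white"),
     c("covariate", "group1_mean", "group2_mean", "smd")]
#>   covariate group1_mean group2_mean           smd
#>         age  80.9491429  80.9481253 -0.0001798430
#>  race:white   0.9418182   0.9418182  0.0000000000
#>   jfi_score   4.6763636   4.6763636  0.0000000000
#>   can_score  59.9272727  59.9127273 -0.0005588447
```

Group 1 is the treated arm; an |SMD| below 0.2 indicates adequate balance.

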