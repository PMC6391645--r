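---
title: "Methods: forecasting the cost-effectiveness of a national mHealth scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting the cost-effectiveness of a national mHealth scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhealthcea)
```

## The problem

`mhealthcea` forecasts the incremental cost-effectiveness of scaling a
combined demand-side (automated maternal voice messaging) and supply-side
(frontline-worker digital client records) mHealth program — the MOTECH
model piloted in Gomoa West District, Ghana — from one district to 170 of
Ghana's 216 districts over a 10-year analytic horizon, against a
status-quo comparator. The pipeline runs from a district registry and an
ingredients-based cost table, through a phased 3-year rollout and
coverage scale-up, to lives saved, DALYs averted, ICERs, and probabilistic
uncertainty analysis. Because the original field data are not publicly
available, a first-class synthetic-data module generates every input the
pipeline consumes.

## Synthetic inputs

`generate_districts()` emulates a census-derived district registry. The
only published district profile is the Gomoa West anchor (population
135,139; 17 CHPS facilities, 1 per 7,949 population; 4 health centers,
1 per 33,785), so:

* populations are drawn log-normally (`sdlog = 0.5`) with mean equal to
  the anchor population — district-size distributions are right-skewed
  and must stay positive;
* CHPS and health-center counts are Poisson with mean
  population/anchor-ratio (at least one CHPS, since a district cannot
  enter the rollout without one);
* nurse counts follow facility counts (3 per CHPS + 8 per health center
  at the anchor — a configurable convention, as no district-level staffing
  is published);
* the crude birth rate is a single national constant (30 per 1,000 per
  year, field-typical for Ghana around 2010), deliberately flat so that
  impact-model behaviour is not confounded with demographic noise;
* regions receive districts proportionally to the rollout plan's regional
  totals, so the reference plan is always feasible.

Setting `pop_sdlog = 0` collapses the generator onto the anchor profile
exactly, which the tests use as an identity case.

`generate_exit_interviews()` stands in for the endline exit-interview
survey behind the effect estimates. Five covariates (education,
employment, marital status, age 15–49, income bracket) enter a single
linear index that drives *both* the treatment-assignment logit
(coefficient 0.8) and the outcome logits (coefficient 0.5), so treated
women are systematically different from controls and the naive
treated−control gap is biased. Conditional on covariates, the treated
outcome probability is the control probability plus the embedded effect
(+0.11 skilled birth attendance, +0.10 facility delivery, +0.06 measles
immunization, on control baselines 0.70 / 0.57 / 0.85), so the true ATT
equals the embedded effect by construction. What the generator does *not*
emulate: cluster sampling, item non-response, measurement error in
self-reported service use, and the convenience-sampling problems of the
original survey — so passing recovery tests show the estimator works on a
correctly specified confounded design, not that the original data were
adequate.

## Effect estimation

`fit_propensity()` is a maximum-likelihood logistic regression of
treatment on the five covariates (marital status as a factor; constant
covariates are dropped to the intercept). Fitted scores are clipped to
`[1e-6, 1 − 1e-6]`; scores at the boundary or a non-converged fit raise a
separation diagnostic rather than an error. `estimate_att()` matches each
treated record, with replacement, to the nearest control by absolute
score distance. Design choices where the procedure was under-specified:

* **with replacement, 1:1** — the standard ATT default, and the estimate
  becomes invariant to record order;
* **ties on distance break to the lowest `record_id`** — reproducibility;
* **default caliper ∞** (none stated); a caliper is exposed and discarded
  treated records are tallied;
* **SE by a 500-resample seeded bootstrap** over matched-pair differences
  (no uncertainty was reported for the original matched effects).

The tests verify parameter recovery (mean ATT within ±0.02 of the
embedded 0.11 over 20 seeds at 5,000 per arm) and that matching debiases
the design while the naive difference stays biased.

## Costing

The cost model is an ingredients approach: 27 activity line items in
three phases — development and start-up (6 months each per district,
one-time capital annualized over the program's life) and implementation
(recurrent). The shipped reference table carries the published 10-year
aggregated amounts; the development-phase items leave a 24,505 USD
residual against their printed subtotal, carried as an explicit
"Unallocated balance" row so phases reconcile.

Aggregated amounts resolve to **fixed unit rates** on the reference
basis: per-district rates for development and start-up (÷170
participating districts → 4,110 and 44,138 USD) and a per-district-year
rate for implementation (÷1,347 district-years, from the 9/8/7
implementation-years of the 45/67/58 annual cohorts → 17,918 USD). Note
the published abstract quotes 17,618 for this figure while the cost table
implies 17,918; the package uses the table value. Resolving to unit rates
(rather than re-spreading the aggregate over whatever schedule is passed)
keeps the stream monotone — adding a district never lowers a year's total
— while reproducing the printed totals exactly under the reference
schedule.

Variable items scale linearly with the district's driver relative to the
anchor: `per_facility` by CHPS + health-center counts, `per_nurse` by
nurse counts, `per_enrollee_year` by population, `lump_total` spread
evenly. Linear scaling is the minimal choice consistent with "costs vary
with facility and nurse counts". Raw expenditures convert to 2014 USD via
month-specific exchange rates and the CPI ratio to 2014
(`adjust_to_base_year()`); the shipped FX/CPI tables are synthetic
fixtures (sources are cited in the literature but rates are not printed).
Capital annualization uses the annuity factor `A·r/(1−(1+r)^−L)` at 3%
per year, end-of-year convention, applied identically to costs and
effects.

## Coverage projection

Coverage gains are linear but attenuate near saturation. The stepping
rule, keyed to start-of-year coverage: full increment at ≤75%, half once
coverage has surpassed 75%, quarter from 90% upward, hard cap at 99%.
Two boundary readings were genuinely open; we key attenuation to
start-of-year coverage (simplest deterministic rule, matches annual
accounting), and we read the 90% clause as *inclusive* (at exactly 90%
the quarter rate applies — the only reading consistent with stepwise
evaluation of the published rules, e.g. 70 → 80 → 85 → 90 → 92.5 → 95 at
+10/yr). The "overall intervention coverage" clause is read per
intervention, the only portfolio computable from stated inputs.

The published inputs give only endline effects (+11/+10/+6 points), not
an annual increment; the reference configuration spreads each effect
linearly over the first 2 post-entry program years. District trajectories
stay at baseline through the district's first active year (gains lag the
development/start-up period; the program saves no lives in Year 1).
Baselines: skilled birth attendance 70% (≈30% of deliveries unattended),
facility delivery 57% and measles 85% (national survey levels of the
period; both configurable).

## Lives saved and DALYs

The published health-effects engine is a proprietary cohort model
(Spectrum/LiST) treated as a black box; this package deliberately
replaces it with a transparent linear attributable-risk engine with a
residual-mortality correction:

> averted = deaths₀ × af × scale × e × (covₜ − cov₀)/100 ÷ (1 − e·cov₀/100)

per intervention–outcome pair, summed over interventions, where `e` is
efficacy and `af` the affected fraction, both in [0, 1]. The denominator
keeps estimates consistent with deaths already prevented by baseline
coverage. Baseline deaths come from a mortality envelope built from
district births (population × CBR), a maternal mortality ratio of
380/100,000 live births, an under-five input of 49/1,000 (the published
infant rate; configurable) and a stillbirth rate of 20/1,000
(field-typical; not published).

Because the engine is simpler than a full cohort model, a **calibration
mode** rescales each outcome's entries so the 10-year national totals hit
supplied anchors (the engine is linear in `af`, so alignment is exact).
The reference anchors are the published per-outcome totals (6,298
maternal; 33,797 child; 19,811 stillbirths → 59,906 lives). Those totals
imply larger attributable fractions than plausible [0, 1] products
support, so calibration raises `af` at most to 1 and carries any excess
in an explicit per-outcome `scale` multiplier — making visible exactly
how far the external anchors sit above what this transparent engine's
plausible parameters produce, rather than hiding it inside an opaque
fraction. The per-year *profile* of lives saved is the engine's own
(driven by the rollout and coverage ramp) and is not forced to match
unpublished per-year values.

DALYs are years of life lost only (no disability weights, no age
weighting), continuously discounted: `deaths × (1 − e^{−rL})/r` at
r = 3%/yr — the standard GBD form — with L = 65.5 years for child deaths
and stillbirths (stillbirths accrue YLLs like neonatal deaths by default;
a switch excludes them) and L = 36.5 for maternal deaths (65.5 minus a
mean maternal age of 29, configurable). At these parameters one child
death averts 28.66 discounted YLLs. The published cumulative DALY total
(1,550,028) cannot be reconstructed from 59,906 deaths under any single
stated (L, r); this engine reports its own total (≈1.68 M; 27.98 DALYs
per life saved, inside the 22–29 bracket the published figures imply)
with all assumptions exposed.

## ICERs and thresholds

`icer()` divides summed incremental costs by summed DALYs averted over a
year or cumulatively, against a status-quo comparator with zero
incremental cost and effect. A scope with positive cost and no effect
(Year 1) yields a typed "undefined (no effect)" record, never an
infinity. `classify_icer()` applies the Commission on Macroeconomics and
Health rule — below 1× per-capita income per DALY averted is highly
cost-effective, below 3× cost-effective — with exact multiples assigned
to the weaker class. `budget_share()` contextualizes per-district costs
against the primary-care share of the national health budget.

## Uncertainty

`make_reference_model()` wraps a solved run into a reduced-form closure —
cost = Σ resolved items; DALYs = Σ per-outcome deaths × per-death YLL —
whose parameters are exactly the quantities the full pipeline computes.
One-way analysis (`one_way()`) re-evaluates the closure at ±20% bounds
(a convention; none published), ranks by ICER span, ties alphabetical.
The probabilistic analysis (`run_psa()`, default 1,000 iterations from a
single seeded stream) samples gammas for cost items (mean = base,
SD = 20% of base) and normals truncated at zero for the per-outcome
lives-saved totals (SD such that the 95% interval spans ±40% of base);
neither family nor spread is published, and all are exposed in the
parameter-spec table. Invalid draws (non-positive effects) are resampled
with a counter; >1% resampling aborts. The point estimate is mean cost ÷
mean effect with a percentile 95% CI; `ceac()` counts net-monetary-benefit
wins on a WTP grid that includes the quoted $50 and $400 thresholds and
the 1×/3× income multiples (1,480 / 4,440); `ce_plane()` buckets draws by
quadrant.

## Problem sizes and numerical choices

The reference run generates 216 districts, rolls out 170, interviews
5,000 women per arm, bootstraps 500 resamples and draws 1,000 PSA
iterations — the full study configuration, which completes in a few
seconds; the test suite exercises smaller configurations of the same code
paths plus the full reference run. Tolerances in tests reflect printed
precision (1 USD on conserved totals, 1 percentage point on shares
printed to the percent, ±0.02 on ATT recovery over 20 seeds). Determinism:
every stochastic stage takes an explicit seed; the pipeline manifest
records MD5 checksums of every output so re-runs are verifiable
bit-for-bit.

## Known limitations

* The lives-saved engine is a calibrated attributable-risk model, not a
  cohort model: per-year totals (e.g. Year-2 lives saved) follow the
  engine's rollout-and-ramp profile and differ from cohort-model outputs.
* Costs are program-perspective only — no client time/travel costs, no
  government salary-scale modelling.
* The district registry, exit interviews and FX/CPI tables are synthetic;
  agreement with their embedded truths says nothing about the original
  field data quality.
* Coverage heterogeneity across districts enters only through rollout
  timing; baselines are national constants.
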