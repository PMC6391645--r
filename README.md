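# mhealthcea

Forecasted cost-effectiveness of scaling a combined maternal-messaging and
frontline-health-worker data mHealth program (the MOTECH model) across
Ghana's districts.

## What it does and for whom

Health-economics analysts and digital-health program planners need to know
whether an mHealth intervention piloted in one district offers value for
money at national scale. `mhealthcea` implements that forecast as a tested,
configurable pipeline:

1. **Synthetic inputs** — a census-like district registry anchored to the
   published Gomoa West profile (population 135,139; 17 CHPS facilities,
   1 per 7,949 population; 4 health centers), and exit-interview records
   with a known embedded treatment effect and deliberate confounding.
2. **Effect estimation** — propensity scores (logistic regression on
   education, employment, marital status, age, income) and 1:1
   nearest-neighbour matching with replacement, yielding the average
   treatment effect on the treated per outcome.
3. **Costing** — an ingredients approach: 27 activity line items in three
   phases (development, start-up, implementation) resolved to per-district
   unit rates and laid onto a phased 3-year rollout of 170 districts
   (cumulative 15/45/84/112/143/170), with variable costs scaling by
   facility, nurse, and population counts, FX/CPI conversion to 2014 USD,
   and 3% annuity-factor annualization of capital.
4. **Coverage projection** — linear gains (+11 skilled birth attendance,
   +10 facility delivery, +6 measles, in percentage points) attenuated at
   breakpoints: full rate at ≤75% coverage, half above 75%, quarter from
   90%, capped at 99%.
5. **Impact** — a transparent attributable-risk lives-saved engine
   (calibrated to per-outcome anchor totals) and YLL-only DALYs:
   `deaths × (1 − e^(−rL))/r` at r = 3%, L = 65.5 years (maternal: 36.5).
6. **CEA and uncertainty** — per-year and cumulative ICERs classified
   against 1×/3× per-capita-income thresholds, a one-way tornado analysis,
   and a 1,000-iteration probabilistic sensitivity analysis with
   cost-effectiveness plane and acceptability curves.

## Worked example

```r
library(mhealthcea)
res <- run_pipeline(default_config(), out_dir = "cea_run")

res$att
#>   outcome              att      se n_matched_pairs n_discarded
#> 1 sba               0.108  0.00767            5000           0
#> 2 facility_delivery 0.0922 0.00918            5000           0
#> 3 measles           0.0646 0.00590            5000           0
```

Matching on 5,000 synthetic records per arm recovers the embedded effects
(0.11 / 0.10 / 0.06) to within sampling error despite the built-in
confounding.

```r
res$impact
#> Impact over 10 years: 59906 deaths averted
#>   (child 33797, maternal 6298, stillbirth 19811), 1676186 DALYs
res$icers[res$icers$scope %in% c("1", "2", "10", "cumulative"), ]
#>        scope incremental_cost dalys_averted cost_per_daly                status
#> 1          1          2243329           0.0            NA undefined (no effect)
#> 2          2          3981217       34864.4     114.19149               defined
#> 3         10          3000481      222810.5      13.46652               defined
#> 4 cumulative         31818765     1676186.4      18.98283               defined
```

Year 1 carries cost but no effect (coverage gains lag the
development/start-up period), so its ICER is a typed *undefined* record;
the cost per DALY averted then falls steeply with scale. The cumulative
~19 USD/DALY sits far below Ghana's per-capita income (US $1,480), i.e.
*highly cost-effective*.

```r
res$psa
#> PSA (1000 draws): cost/DALY 19.21 (95% CI 14.32-27.35), cost/death 537.29
ceac(res$psa, c(50, 400, 1480))
#>     wtp probability
#> 1    50           1
#> 2   400           1
#> 3  1480           1
```

All 1,000 probabilistic draws land in the northeast quadrant of the
cost-effectiveness plane, and the program is cost-effective with
probability 1 from a willingness to pay of US $50 per DALY averted
upward. `plot_ce_plane()`, `plot_ceac()` and `plot_tornado()` draw the
standard figures.

A single piece of the machinery is just as usable on its own, e.g. the
breakpoint-attenuated coverage projection:

```r
project_coverage(70, 10, 5)$values
#> [1] 80.0 85.0 90.0 92.5 95.0
```

Every run writes its stage outputs (`districts.csv`, `effects.json`,
`cost_stream.csv`, `coverage.csv`, `impact.csv`, `icers.csv`,
`psa_draws.csv`, `ceac.csv`, `tornado.csv`) plus a `manifest.json` with
per-file MD5 checksums; identical config and seed reproduce identical
checksums. Note the cost table's implied sustaining cost is US
$17,918/district/year (the abstract-level figure of 17,618 elsewhere in
the literature is a known discrepancy; the table value is used).

See `vignettes/cea-methods.Rmd` for the model, its assumptions, and every
numerical choice.

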