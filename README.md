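# strokecea

Lifetime cost-effectiveness modelling for cytoprotective therapy in
acute ischemic stroke, from the perspective of the Chinese healthcare
system (2021 CNY).

## The problem

Two cytoprotective drugs compete for the same indication: edaravone
dexborneol (`edb`) and human urinary kallidinogenase (`huk`). Their
pivotal evidence comes from different single-arm populations, and the
clinical benefit — a shift in the 90-day modified Rankin Scale (mRS)
distribution toward less disability — plays out over a patient's
remaining lifetime through disability-dependent survival, stroke
recurrence, long-term care costs and quality of life. `strokecea`
implements the full decision-analytic pipeline for that comparison:

- a **90-day decision tree** (drug acquisition, acute hospitalization,
  first-year outcomes) chained to a **40-year Markov cohort model** over
  the seven mRS states, with Chinese life-table mortality adjusted by
  mRS-specific hazard ratios, annual recurrence with post-recurrence
  redistribution, 5% discounting and half-cycle correction;
- **economic comparison**: incremental cost-effectiveness ratio (ICER),
  net monetary benefit (NMB) at a willingness-to-pay threshold of
  ¥80,976 per QALY, and dominance classification;
- **sensitivity analysis**: one-way deterministic (tornado) and
  probabilistic (second-order Monte Carlo with gamma/beta/lognormal
  distributions, cost-effectiveness plane and acceptability curve);
- an **unanchored matching-adjusted indirect comparison (MAIC)**:
  method-of-moments propensity weighting of individual patient data to
  thirteen aggregate baseline targets, including median matching, with
  effective-sample-size diagnostics;
- a **synthetic individual-patient-data generator** calibrated to the
  published baseline summaries, so the matching pipeline can be
  exercised end to end without access to trial data.

The packaged base case (`default_params()`) encodes the published
inputs of the corresponding evaluation; everything is data-frame-first,
returns tibbles, and supports `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(strokecea)

base <- run_base_case()
base
#> <cea_result: edb vs huk>
#>   incremental: 0.1297 QALYs, 819 CNY
#>   ICER: 6,315 CNY/QALY (WTP 80,976)
#>   incremental NMB: 9,683 CNY

tidy(base)
#> # A tibble: 7 × 4
#>   quantity         edb       huk incremental
#>   <chr>          <dbl>     <dbl>       <dbl>
#> 1 qalys           7.67      7.54       0.130
#> 2 cost_total  28447.    27628.       819.
#> 3 cost_drug    2772      2100        672
#> 4 cost_hosp   17779.    17691.        88.6
#> 5 cost_post    7896.     7837.        58.5
#> 6 nmb        592380.   582697.      9683.
#> 7 icer           NA        NA       6315.
```

Edaravone dexborneol gains about 0.130 QALYs for an extra ¥819 — an
ICER of ¥6,315 per QALY, far below the threshold. One-way sensitivity
analysis shows the mRS 2 utility is the most influential parameter:

```r
dsa <- run_dsa(default_params())
head(dsa, 3)
#> # A tibble: 3 × 10
#>   parameter       base   low  high icer_base icer_low icer_high ...
#> 1 u_mrs2          0.67  0.48  0.86     6315.    3443.    38055.
#> 2 drug_price_edb 33    33    49       6315.    6315.    16678.
#> 3 u_mrs3          0.44  0.2   0.68     6315.   14280.     4054.
autoplot(dsa)   # tornado diagram
```

Probabilistic sensitivity analysis (1,000 iterations) finds the
intervention cost-effective at the threshold in every draw:

```r
psa <- run_psa(default_params(), n_iter = 1000, seed = 1)
psa$p_ce_at_wtp
#> [1] 1
plot_ceac(psa)
```

And the matching stage, on a synthetic cohort of 1,200 patients:

```r
ipd <- generate_ipd(ipd_generator_spec(n = 1200, seed = 20260101))
m <- maic(ipd)
m
#> <stroke_maic: n = 1200, ESS = 221.9>
#>   max weighted-moment gap: 8.5e-13 after 8 iterations
#>   weighted mRS D90 distribution:
#>   mrs0   mrs1   mrs2   mrs3   mrs4   mrs5   mrs6
#> 0.2044 0.4005 0.1612 0.0967 0.1074 0.0297 0.0000
```

All thirteen weighted baseline moments hit their targets to within
1e-12; the effective sample size (222 of 1,200) quantifies the
population overlap.

## License

MIT.
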