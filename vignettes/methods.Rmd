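---
title: "Model structure, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## Scope

`strokecea` implements a lifetime cost-utility comparison of two
cytoprotective drug strategies for acute ischemic stroke — edaravone
dexborneol (`edb`) and human urinary kallidinogenase (`huk`) — from the
perspective of the Chinese healthcare system, in 2021 CNY. The packaged
base case (`default_params()`) encodes the published inputs of that
evaluation: 90-day modified Rankin Scale (mRS) outcome distributions per
arm, health-state utilities, Chinese life-table mortality with
mRS-specific hazard ratios, annual stroke-recurrence risks with a
post-recurrence redistribution, and acute plus long-term costs.

Because several computational conventions of the original evaluation are
not pinned down by its report, this vignette states exactly which
conventions this package uses, why, and where results are therefore
expected to differ at the margin.

## Model structure

**Decision-tree stage (first 90 days).** Each arm starts from a common
split between patients who survive with mRS 0–5 and early deaths, then
lands on its arm-specific 90-day mRS distribution. The stage contributes
the drug-acquisition cost (units × price × treatment days; ¥2,772 for
`edb`, ¥2,100 for `huk`) and the acute hospitalization cost, priced from
the 90-day split between mRS 0–2, mRS 3–5 and death.

**Markov stage (years 1–40).** The 90-day distribution seeds a cohort
that transitions annually between the seven mRS states, with mRS 6
(death) absorbing and no improvement in mRS permitted. Each cycle, in
order:

1. **Death** from background mortality adjusted by the state's hazard
   ratio (see below).
2. **Recurrence** among survivors, at the year-specific annual
   probability (year 10 onwards reuses the year-10 value).
3. **Redistribution** of recurring patients over equal-or-worse mRS
   states according to the post-recurrence columns, whose common
   complement (17.83%) is recurrence case fatality.

Cycle *k* uses the mortality of age 60 + (*k* − 1), i.e. the risk in
force *during* the year being simulated.

## Conventions

These choices are deliberate and switchable where noted:

- **Hazard ratios act on the rate scale** by default:
  *p* = 1 − (1 − *q*)^HR. This keeps probabilities in [0, 1] at high
  ages where the naive product *q* × HR exceeds 1. The naive convention
  is available as `hr_mode = "probability"` (capped at 1) on the engine
  and analysis functions.
- **Half-cycle correction** is trapezoidal: state-membership accruals
  (utilities, annual post-stroke costs) are weighted
  (0.5, 1, …, 1, 0.5) across cycles 0–40. One-time event costs
  (acute episode, recurrence episodes) are not half-cycle weighted.
- **Discounting** is annual at 5% for both costs and outcomes,
  (1 + *r*)^−*k*, with cycle 0 undiscounted.
- **Post-stroke annual costs are charged per stroke-year**, not for
  every year lived: the index year charges each survivor group once, and
  each recurrence triggers one further year of post-stroke cost in the
  post-recurrence group. This reading reproduces the published per-arm
  cost decomposition (≈ ¥7.9k long-term care per arm); charging the
  annual cost for all remaining life-years would give ≈ ¥108k and is
  plainly not what the published totals contain.
- **Recurrence deaths** incur the death-related hospitalization cost;
  recurrence survivors incur the stroke disutility for that year, as do
  all survivors in the index year.

## Base-case results

```{r base}
base <- run_base_case()
tidy(base)
```

With the packaged inputs these conventions give an incremental gain of
about 0.130 QALYs at an extra cost of about ¥819, an ICER of roughly
¥6,315 per QALY — far below the threshold of ¥80,976 (three times 2021
GDP per capita) — and positive incremental net monetary benefit.

A note on fidelity: the published evaluation reports a slightly larger
QALY gain (0.153). That figure is not recoverable from the *printed*
90-day distributions, which are rounded to 0.1%: the maximum incremental
QALYs attainable from the printed inputs across every defensible
convention combination is about 0.14. The original computation evidently
used unrounded internal outcome distributions; between-arm differences
this small sit within the rounding noise of the published inputs. Per-arm
absolute results (QALYs ≈ 7.67 / 7.54, costs ≈ ¥28.4k / ¥27.6k) and all
qualitative conclusions agree.

## Sensitivity analysis

`run_dsa()` re-runs the model at each parameter's one-way bounds and
sorts by ICER span (the tornado order); the mRS 2 utility dominates
because the arms differ most in the share of patients left with moderate
disability. `run_psa()` draws gamma (costs), beta (utilities,
disutility) and lognormal (hazard ratios) parameters independently,
evaluates both arms under the *same* draw, and summarises the
cost-effectiveness plane and acceptability curve. Drug prices and
discount rates are varied deterministically only. Seeds are explicit and
results are fully reproducible.

```{r psa, eval = FALSE}
psa <- run_psa(default_params(), n_iter = 1000, seed = 1)
psa$p_ce_at_wtp        # probability cost-effective at 80,976 CNY/QALY
autoplot(psa)          # cost-effectiveness plane
plot_ceac(psa)         # acceptability curve
```

## Matching-adjusted indirect comparison

The two arms come from different single-arm evidence, so the
intervention's individual patient data are reweighted to the
comparator trial's aggregate baseline (13 covariates) before comparing
outcomes — an unanchored MAIC. Weights are
*w*~i~ = exp(*Z*~i~ *b*) with *b* minimising the convex objective
Σ exp(*Z*~i~ *b*); at the optimum every weighted moment of the centred
design matrix is zero, i.e. every matched summary equals its target.
The solver is damped Newton with analytic gradient and Hessian (BFGS
fallback), converging to weighted-moment gaps near machine precision in
a handful of iterations. Medians are matched via the indicator transform
I[*x* ≤ median] − 0.5 (weighted share at or below the target median
equals one half), since moment matching cannot constrain a median
directly. `effective_sample_size()` reports the usual
(Σ*w*)² / Σ*w*² diagnostic.

## Synthetic individual patient data

Real trial IPD cannot ship with the package, so `generate_ipd()` draws a
synthetic cohort whose *marginals* target the intervention arm's
published baseline summaries: truncated normals for age and BMI, a
median-calibrated scaled beta for onset-to-treatment time, a truncated
geometric NIHSS, and Bernoulli indicators. Two designed dependencies
make the data non-trivial to reweight: coronary heart disease rises with
age through a logistic link (intercept re-centred so the marginal stays
on target), and the 90-day mRS outcome follows a proportional-odds model
whose latent score worsens with NIHSS, age and diabetes. Cutpoints are
root-found against the realised linear predictors so the sample-average
category probabilities reproduce the target outcome margins. The
generator emulates marginal structure and plausible dependence — not the
full joint distribution of any real trial — which is sufficient for
exercising the matching pipeline end to end.

## Numerical choices

- Cohort propagation is exact linear algebra on 7-state row-stochastic
  matrices; no simulation error enters the deterministic results. The
  test suite cross-checks the trace against a 200,000-walker
  individual-level microsimulation.
- Root-finding (beta shape for the treatment-time median, logistic
  intercepts, proportional-odds cutpoints) uses `uniroot()` on monotone
  objectives with tight tolerances; the beta inversion goes through
  `pbeta()` rather than `qbeta()` for stability at extreme shapes.
- All headline statistics are computed at full precision; rounding is
  left to printing.

## Limitations

- The published QALY gain is not exactly reproducible from printed
  inputs (see above); incremental results carry that caveat while
  per-arm results do not.
- Utilities are drawn independently in the PSA, so draws need not stay
  monotone across mRS states; this mirrors independent published
  distributions rather than imposing a joint prior.
- The model permits no mRS improvement after 90 days and applies a
  single recurrence redistribution regardless of age or time since
  index stroke.
- Cumulative 40-year mortality here reaches ≈ 99.6% per arm; claims
  that essentially the whole cohort has died by the horizon hold, but a
  strict > 99.7% bound does not under these conventions.
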