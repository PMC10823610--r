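# Base-case parameter set for the acute-ischemic-stroke cost-effectiveness
# model: edaravone dexborneol (edb) vs human urinary kallidinogenase (huk).
# All currency in 2021 Chinese Yuan; probabilities as fractions.
d90:
  # 90-day mRS 0..6 distribution per arm (MAIC-adjusted indirect comparison)
  edb: [0.202, 0.406, 0.120, 0.193, 0.048, 0.031, 0.000]
  huk: [0.190, 0.375, 0.178, 0.160, 0.083, 0.013, 0.001]
initial_split:
  # baseline mRS split of patients entering the decision tree
  mrs0: 0.903
  mrs1: 0.097
costs:
  drug:
    edb: {unit_price: 33, units_per_day: 6, treatment_days: 14}
    huk: {unit_price: 100, units_per_day: 1, treatment_days: 21}
  hospital_days: 9.9   # descriptive input; no formula consumes it
  hospitalization:
    mrs0_2: 12614
    mrs3_5: 17223
    mrs6: 13951
  post_stroke_annual:
    mrs0_2: 9264
    mrs3_5: 14238
utilities:
  mrs0: 0.95
  mrs1: 0.89
  mrs2: 0.67
  mrs3: 0.44
  mrs4: 0.16
  mrs5: 0.10
  stroke_disutility: 0.086
mortality:
  # annual natural mortality by age band (China life table)
  life_table:
    - {age_low: 60, age_high: 64, rate: 0.0075}
    - {age_low: 65, age_high: 69, rate: 0.0117}
    - {age_low: 70, age_high: 74, rate: 0.0203}
    - {age_low: 75, age_high: 79, rate: 0.0356}
    - {age_low: 80, age_high: 84, rate: 0.0629}
    - {age_low: 85, age_high: 89, rate: 0.1028}
    - {age_low: 90, age_high: .inf, rate: 0.1617}
  # mRS-state-specific hazard ratio vs the general population
  hazard_ratio: [1.53, 1.52, 2.17, 3.18, 4.55, 6.55]
recurrence:
  # annual recurrent-stroke probability by years since the index stroke;
  # the last entry applies to all later years
  annual_prob: [0.059, 0.036, 0.025, 0.022, 0.022, 0.027, 0.027, 0.023, 0.028, 0.016]
  # post-recurrence mRS redistribution: one column per pre-recurrence state
  # mRS 0..5, rows = post-recurrence mRS 0..5; the per-column remainder to 1
  # is the within-cycle recurrence case fatality
  redistribution:
    mrs0: [0.1782, 0.2277, 0.0891, 0.1188, 0.1386, 0.0693]
    mrs1: [0.0,    0.4059, 0.0891, 0.1188, 0.1386, 0.0693]
    mrs2: [0.0,    0.0,    0.4950, 0.1188, 0.1386, 0.0693]
    mrs3: [0.0,    0.0,    0.0,    0.6138, 0.1386, 0.0693]
    mrs4: [0.0,    0.0,    0.0,    0.0,    0.7524, 0.0693]
    mrs5: [0.0,    0.0,    0.0,    0.0,    0.0,    0.8217]
economics:
  discount_rate_cost: 0.05
  discount_rate_outcome: 0.05
  wtp: 80976            # 1x GDP per capita, 2021 CNY per QALY
  horizon_cycles: 40
  cycle_length: 1
  start_age: 60
psa:
  # second-order Monte Carlo sampling distributions (Table-style alpha/beta):
  # gamma: shape/scale, beta: shape1/shape2, lognormal: meanlog/sdlog
  - {parameter: cost_hosp_mrs0_2, family: gamma, alpha: 17494.59, beta: 0.72}
  - {parameter: cost_hosp_mrs3_5, family: gamma, alpha: 7860.91, beta: 2.19}
  - {parameter: cost_hosp_mrs6, family: gamma, alpha: 548.15, beta: 25.45}
  - {parameter: cost_post_mrs0_2, family: gamma, alpha: 3909.41, beta: 2.37}
  - {parameter: cost_post_mrs3_5, family: gamma, alpha: 1235.08, beta: 11.53}
  - {parameter: u_mrs0, family: beta, alpha: 56315.05, beta: 2963.95}
  - {parameter: u_mrs1, family: beta, alpha: 10469.23, beta: 1293.95}
  - {parameter: u_mrs2, family: beta, alpha: 803.62, beta: 395.81}
  - {parameter: u_mrs3, family: beta, alpha: 172.72, beta: 219.83}
  - {parameter: u_mrs4, family: beta, alpha: 126.72, beta: 665.28}
  - {parameter: u_mrs5, family: beta, alpha: 7.68, beta: 69.10}
  - {parameter: stroke_disutility, family: beta, alpha: 38.33, beta: 407.36}
  - {parameter: hr_mrs0, family: lognormal, alpha: 0.43, beta: 0.10}
  - {parameter: hr_mrs1, family: lognormal, alpha: 0.42, beta: 0.11}
  - {parameter: hr_mrs2, family: lognormal, alpha: 0.77, beta: 0.01}
  - {parameter: hr_mrs3, family: lognormal, alpha: 1.16, beta: 0.002}
  - {parameter: hr_mrs4, family: lognormal, alpha: 1.52, beta: 0.03}
  - {parameter: hr_mrs5, family: lognormal, alpha: 1.88, beta: 0.03}
dsa:
  # one-way deterministic sensitivity ranges
  - {parameter: drug_price_edb, low: 33, high: 49}
  - {parameter: drug_price_huk, low: 90, high: 100}
  - {parameter: cost_hosp_mrs0_2, low: 12428, high: 12802}
  - {parameter: cost_hosp_mrs3_5, low: 16845, high: 17606}
  - {parameter: cost_hosp_mrs6, low: 12819, high: 15155}
  - {parameter: cost_post_mrs0_2, low: 8977, high: 9558}
  - {parameter: cost_post_mrs3_5, low: 13460, high: 15049}
  - {parameter: u_mrs0, low: 0.90, high: 1.00}
  - {parameter: u_mrs1, low: 0.78, high: 1.00}
  - {parameter: u_mrs2, low: 0.48, high: 0.86}
  - {parameter: u_mrs3, low: 0.20, high: 0.68}
  - {parameter: u_mrs4, low: 0.00, high: 0.35}
  - {parameter: u_mrs5, low: 0.00, high: 0.28}
  - {parameter: stroke_disutility, low: 0.060, high: 0.112}
  - {parameter: hr_mrs0, low: 1.23, high: 1.83}
  - {parameter: hr_mrs1, low: 1.20, high: 1.83}
  - {parameter: hr_mrs2, low: 2.14, high: 2.20}
  - {parameter: hr_mrs3, low: 3.17, high: 3.19}
  - {parameter: hr_mrs4, low: 4.31, high: 4.78}
  - {parameter: hr_mrs5, low: 6.12, high: 6.98}
  - {parameter: discount_rate_cost, low: 0.00, high: 0.08}
  - {parameter: discount_rate_outcome, low: 0.00, high: 0.08}
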