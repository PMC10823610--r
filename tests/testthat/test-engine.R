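test_that("life-table lookup respects age bands", {
  expect_equal(natural_mortality(60, fixture), 0.0075)
  expect_equal(natural_mortality(64, fixture), 0.0075)
  expect_equal(natural_mortality(65, fixture), 0.0117)
  expect_equal(natural_mortality(95, fixture), 0.1617)
  expect_equal(natural_mortality(c(60, 72, 100), fixture),
               c(0.0075, 0.0203, 0.1617))
  expect_error(natural_mortality(40, fixture), "start age")
})

test_that("excess mortality acts on the hazard scale by default", {
  # HR = 1 recovers the life-table probability exactly
  p <- fixture
  p$mortality$hazard_ratio[] <- 1
  expect_equal(death_probability(60, 0:5, p), rep(0.0075, 6))
  # closed form 1 - (1 - q)^HR
  expect_equal(death_probability(60, 5, fixture), 1 - (1 - 0.0075)^6.55)
  expect_equal(death_probability(60, 5, fixture), 0.0481, tolerance = 1e-3)
  # at high ages the naive product exceeds 1; the rate-scale result must not
  expect_equal(death_probability(95, 5, fixture), 0.685, tolerance = 1e-3)
  expect_lt(death_probability(95, 5, fixture), 1)
  expect_equal(death_probability(95, 5, fixture, hr_mode = "probability"), 1)
})

test_that("recurrence risk follows years since the index stroke", {
  expect_equal(recurrence_probability(1, fixture), 0.059)
  expect_equal(recurrence_probability(9, fixture), 0.028)
  expect_equal(recurrence_probability(c(10, 25, 40), fixture), rep(0.016, 3))
  expect_error(recurrence_probability(0, fixture))
})

test_that("transition matrices are row-stochastic with absorbing death", {
  for (k in c(1, 2, 5, 10, 25, 40)) {
    M <- build_transition_matrix(k, fixture)
    expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-9)
    expect_true(all(M >= 0))
    expect_equal(unname(M[7, ]), c(0, 0, 0, 0, 0, 0, 1))
    # no improvement transitions among alive states
    expect_true(all(M[1:6, 1:6][row(M[1:6, 1:6]) > col(M[1:6, 1:6])] == 0))
  }
})

test_that("no-recurrence limit reduces transitions to pure survival", {
  p <- fixture
  p$recurrence$annual_prob[] <- 0
  p$mortality$hazard_ratio[] <- 1
  M <- build_transition_matrix(1, p)
  q <- natural_mortality(60, p)
  for (s in 1:6) {
    expect_equal(unname(M[s, s]), 1 - q)
    expect_equal(unname(M[s, 7]), q)
  }
})

test_that("recurrence branch of the transition matrix follows the redistribution column", {
  # origin mRS 2 at cycle 1: survivors split over states 2..5 per the
  # configured column, with the case-fatality remainder going to death
  M <- build_transition_matrix(1, fixture)
  pd <- death_probability(60, 2, fixture)
  rk <- recurrence_probability(1, fixture)
  surv <- 1 - pd
  expect_equal(unname(M["mrs2", "mrs3"]), surv * rk * 0.1188)
  expect_equal(unname(M["mrs2", "mrs4"]), surv * rk * 0.1386)
  expect_equal(unname(M["mrs2", "mrs5"]), surv * rk * 0.0693)
  expect_equal(unname(M["mrs2", "mrs2"]), surv * (1 - rk) + surv * rk * 0.4950)
  expect_equal(unname(M["mrs2", "mrs6"]), pd + surv * rk * (1 - 0.8217),
               tolerance = 1e-6)
})

test_that("decision tree prices the acute episode from the 90-day split", {
  huk <- decision_tree_stage("huk", fixture)
  expect_equal(huk$drug_cost, 2100)           # 100 x 1 x 21
  edb <- decision_tree_stage("edb", fixture)
  expect_equal(edb$drug_cost, 2772)           # 33 x 6 x 14
  expect_equal(edb$hospitalization_cost,
               0.728 * 12614 + 0.272 * 17223, tolerance = 1e-9)
  expect_error(decision_tree_stage("placebo", fixture), "unknown arm")
})

test_that("a cohort starting dead accrues no quality-adjusted time", {
  p <- fixture
  dead <- mrs_distribution(c(0, 0, 0, 0, 0, 0, 1))
  p$d90$edb <- dead
  tree <- decision_tree_stage("edb", p)
  expect_equal(tree$first_year_qalys, 0)
  out <- run_arm("edb", p)
  expect_equal(out$qalys, 0)
  expect_equal(out$life_years, 0)
  expect_equal(out$cost_total, out$cost_drug + 13951)  # mRS6 hospitalization only
})

test_that("cohort trace conserves probability and is monotone", {
  for (arm in c("edb", "huk")) {
    tr <- run_cohort(arm, fixture)
    occ <- as.matrix(tr[, paste0("mrs", 0:6)])
    expect_equal(unname(rowSums(occ)), rep(1, 41), tolerance = 1e-9)
    expect_true(all(diff(occ[, 7]) >= 0))   # death absorbs
    expect_true(all(diff(occ[, 1]) <= 0))   # no improvement into mRS 0
    expect_gt(occ[41, 7], 0.99)             # nearly everyone dies in 40 years
    expect_equal(tr$age, 60:100)
  }
})

test_that("frozen dynamics leave occupancy constant", {
  p <- frozen_cohort_params()
  tr <- run_cohort("edb", p)
  occ <- as.matrix(tr[, paste0("mrs", 0:6)])
  for (k in 2:41) expect_equal(occ[k, ], occ[1, ], tolerance = 1e-12)
})

test_that("cohort trace agrees with an individual-level microsimulation", {
  for (seed in c(11, 22, 33)) {
    ms <- microsim_occupancy("edb", fixture, n_walkers = 200000, seed = seed)
    tr <- run_cohort("edb", fixture)
    occ <- as.matrix(tr[, paste0("mrs", 0:6)])
    expect_lt(max(abs(ms - occ)), 0.005)
  }
})

test_that("discounting never increases totals and vanishes at rate zero", {
  p0 <- fixture
  p0$economics$discount_rate_cost <- 0
  p0$economics$discount_rate_outcome <- 0
  disc <- run_arm("edb", fixture)
  undisc <- run_arm("edb", p0)
  expect_gt(undisc$qalys, disc$qalys)
  expect_gt(undisc$cost_total, disc$cost_total)
  # undiscounted QALYs equal the raw half-cycle-weighted utility sum
  occ <- as.matrix(undisc$trace[, paste0("mrs", 0:6)])
  u <- p0$utilities$u
  w <- c(0.5, rep(1, 39), 0.5)
  dis <- c((1 - occ[1, 7]), attr(undisc$trace, "recurrence_survivors")[-1]) *
    p0$utilities$stroke_disutility
  expect_equal(undisc$qalys, sum(w * (as.numeric(occ[, 1:6] %*% u) - dis)),
               tolerance = 1e-12)
})

test_that("life-years decrease when any hazard ratio rises", {
  base <- run_arm("huk", fixture)
  for (id in c("hr_mrs0", "hr_mrs3", "hr_mrs5")) {
    p <- set_parameter(fixture, id, get_parameter(fixture, id) * 1.5)
    expect_lt(run_arm("huk", p)$life_years, base$life_years)
  }
})

test_that("cost components add up to the total", {
  for (arm in c("edb", "huk")) {
    out <- run_arm(arm, fixture)
    expect_equal(out$cost_total, out$cost_drug + out$cost_hosp + out$cost_post)
    expect_gt(out$qalys, 0)
    expect_lt(out$qalys, out$life_years)
  }
})
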