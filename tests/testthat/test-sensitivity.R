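test_that("one-way analysis covers every configured range and sorts by span", {
  dsa <- run_dsa(fixture)
  expect_s3_class(dsa, "stroke_dsa")
  expect_setequal(dsa$parameter, fixture$dsa$parameter)
  expect_true(all(diff(dsa$span) <= 0))
  expect_equal(dsa$span, abs(dsa$icer_high - dsa$icer_low))
  # every run shares the same base-case ICER
  expect_equal(unique(dsa$icer_base), run_base_case(fixture)$icer)
})

test_that("one-way results respond in the economically expected direction", {
  dsa <- run_dsa(fixture)
  row <- function(id) dsa[dsa$parameter == id, ]
  # a dearer intervention drug raises the ICER; a dearer comparator drug
  # lowers it (both configured ranges are one-sided with a bound at base)
  edb <- row("drug_price_edb")
  expect_equal(edb$icer_low, edb$icer_base)   # low bound = base price
  expect_gt(edb$icer_high, edb$icer_base)
  huk <- row("drug_price_huk")
  expect_gt(huk$icer_low, huk$icer_base)
  expect_equal(huk$icer_high, huk$icer_base)  # high bound = base price
  # the mRS 2 utility drives the largest swing: the arms differ most in the
  # share of patients left with moderate disability
  expect_equal(dsa$parameter[1], "u_mrs2")
})

test_that("a null range leaves the ICER at its base value", {
  p <- fixture
  p$dsa <- tibble::tibble(parameter = "u_mrs1", low = 0.89, high = 0.89)
  dsa <- run_dsa(p)
  expect_equal(dsa$icer_low, dsa$icer_base)
  expect_equal(dsa$icer_high, dsa$icer_base)
  expect_equal(dsa$span, 0)
})

test_that("infeasible ranges are skipped with a warning, not silently dropped", {
  p <- fixture
  p$dsa <- tibble::tibble(parameter = c("u_mrs1", "u_mrs0"),
                          low = c(0.80, 0.9), high = c(1.7, 0.98))
  expect_warning(dsa <- run_dsa(p), "u_mrs1")
  expect_equal(dsa$parameter, "u_mrs0")
})

test_that("parameter draws reproduce the configured distributions", {
  # 10,000 draws per parameter: empirical centres within 2% of the base case
  set.seed(404)
  n_draw <- 10000
  spec <- fixture$psa
  draws <- matrix(NA_real_, n_draw, nrow(spec))
  for (i in seq_len(n_draw)) {
    p <- sample_parameter_set(fixture)
    draws[i, ] <- vapply(spec$parameter, get_parameter, numeric(1), params = p)
  }
  for (j in seq_len(nrow(spec))) {
    base <- get_parameter(fixture, spec$parameter[j])
    centre <- switch(spec$family[j],
                     gamma = mean(draws[, j]),
                     beta = mean(draws[, j]),
                     lognormal = stats::median(draws[, j]))
    expect_lt(abs(centre - base) / base, 0.02)
    # type invariants hold draw by draw
    if (spec$family[j] == "beta") expect_true(all(draws[, j] >= 0 & draws[, j] <= 1))
    if (spec$family[j] == "gamma") expect_true(all(draws[, j] >= 0))
    if (spec$family[j] == "lognormal") expect_true(all(draws[, j] > 0))
  }
  # drug prices and discount rates are fixed by design
  expect_false(any(c("drug_price_edb", "discount_rate_cost") %in% spec$parameter))
})

test_that("probabilistic analysis is reproducible and seed-sensitive", {
  a <- run_psa(fixture, n_iter = 20, seed = 77)
  b <- run_psa(fixture, n_iter = 20, seed = 77)
  expect_equal(a$draws, b$draws)
  expect_equal(a$ceac, b$ceac)
  c_ <- run_psa(fixture, n_iter = 20, seed = 78)
  expect_false(isTRUE(all.equal(a$draws$dqalys, c_$draws$dqalys)))
  expect_error(run_psa(fixture, n_iter = 20), "seed")
})

test_that("the acceptability curve is a proper monotone summary of the draws", {
  psa <- run_psa(fixture, n_iter = 200, seed = 31)
  expect_equal(nrow(psa$draws), 200)
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
  # here higher thresholds can only help: gains are positive in virtually
  # every draw, so check monotonicity empirically against the draws
  by_hand <- vapply(psa$ceac$wtp,
                    function(l) mean(psa$draws$dqalys * l - psa$draws$dcost > 0),
                    numeric(1))
  expect_equal(psa$ceac$probability, by_hand)
  expect_equal(psa$ceac$wtp[1], 0)
  expect_true(fixture$economics$wtp %in% psa$ceac$wtp)
  expect_equal(psa$p_ce_at_wtp,
               psa$ceac$probability[psa$ceac$wtp == fixture$economics$wtp])
})

test_that("degenerate sampling (no distributions) collapses to the base case", {
  p <- fixture
  p$psa <- p$psa[0, ]
  psa <- run_psa(p, n_iter = 5, seed = 1)
  g <- glance(run_base_case(fixture))
  expect_equal(psa$draws$dcost, rep(g$incremental_cost, 5))
  expect_equal(psa$draws$dqalys, rep(g$incremental_qalys, 5))
})

test_that("tidy and glance expose the draws and the headline probability", {
  psa <- run_psa(fixture, n_iter = 50, seed = 5)
  td <- tidy(psa)
  expect_named(td, c("iteration", "dcost", "dqalys", "icer"))
  g <- glance(psa)
  expect_equal(g$n_iter, 50)
  expect_equal(g$icer_of_means, mean(td$dcost) / mean(td$dqalys))
  expect_equal(g$p_ce_at_wtp, psa$p_ce_at_wtp)
})
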