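toy_ipd <- function(n = 40, seed = 5) {
  set.seed(seed)
  tibble::tibble(
    x = stats::rnorm(n),
    z = stats::rbinom(n, 1, 0.4),
    mrs_d90 = sample(0:4, n, replace = TRUE)
  )
}

test_that("matching targets already met yield uniform weights", {
  ipd <- toy_ipd()
  targets <- tibble::tibble(
    covariate = c("x", "z"), type = c("mean", "proportion"),
    value = c(mean(ipd$x), mean(ipd$z))
  )
  prep <- prepare_matching_matrix(ipd, targets)
  w <- fit_maic_weights(prep$Z)
  expect_equal(as.numeric(w), rep(1, nrow(ipd)), tolerance = 1e-6)
  expect_equal(effective_sample_size(w), nrow(ipd), tolerance = 1e-6)
})

test_that("one-moment problem reproduces the closed-form weight ratio", {
  # two patients {0, 1}, target mean 0.75: solving the single moment
  # equation w1(0 - .75) + w2(1 - .75) = 0 gives w2/w1 = 3
  Z <- matrix(c(0, 1) - 0.75, ncol = 1)
  w <- fit_maic_weights(Z)
  expect_equal(w[[2]] / w[[1]], 3, tolerance = 1e-8)
  expect_equal(as.numeric(w), c(0.5, 1.5), tolerance = 1e-8)
})

test_that("effective sample size follows its defining formula", {
  expect_equal(effective_sample_size(rep(2, 10)), 10)
  expect_equal(effective_sample_size(c(1, 0, 0, 0)), 1)
  expect_equal(effective_sample_size(c(0.5, 1.5)), 1.6)
  expect_error(effective_sample_size(c(0, 0)), "zero")
  expect_error(effective_sample_size(c(-1, 1)), "non-negative")
})

test_that("design-matrix construction validates its inputs", {
  ipd <- toy_ipd()
  expect_error(
    prepare_matching_matrix(ipd, tibble::tibble(covariate = "missing_cov",
                                                type = "mean", value = 0)),
    "absent")
  ipd_na <- ipd; ipd_na$x[3] <- NA
  expect_error(
    prepare_matching_matrix(ipd_na, tibble::tibble(covariate = "x",
                                                   type = "mean", value = 0)),
    "missing values")
  ipd_const <- ipd; ipd_const$z <- 1
  expect_error(
    prepare_matching_matrix(ipd_const, tibble::tibble(covariate = "z",
                                                      type = "proportion",
                                                      value = 0.4)),
    "unmatchable")
  expect_error(
    prepare_matching_matrix(ipd, tibble::tibble(covariate = "x",
                                                type = "proportion",
                                                value = 0.4)),
    "indicator")
})

test_that("solver matches a derivative-free optimizer on small instances", {
  set.seed(17)
  Z <- cbind(stats::rnorm(60) - 0.3, stats::rbinom(60, 1, 0.5) - 0.35)
  w <- fit_maic_weights(Z)
  b <- attr(w, "b")
  q_fun <- function(b) sum(exp(drop(Z %*% b)))
  opt <- stats::optim(c(0, 0), q_fun, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(b, opt$par, tolerance = 1e-5)
})

test_that("weighted moments hit every aggregate target on synthetic data", {
  ipd <- generate_ipd(ipd_generator_spec(n = 1200, seed = 20260101))
  m <- maic(ipd)
  expect_true(all(abs(m$balance$gap) < 1e-6))
  expect_lte(m$ess, m$n)
  expect_gt(m$ess, 0)
  expect_equal(mean(m$weights), 1, tolerance = 1e-12)
  expect_true(all(m$weights >= 0))
  expect_equal(sum(m$weighted_outcome), 1, tolerance = 1e-12)
})

test_that("reweighting shifts outcomes in the direction of the severity targets", {
  # targets demand a higher NIHSS (median 7 vs 6) and more diabetes, both of
  # which worsen the latent outcome score, so weighted mass must move from
  # mRS 0-1 toward mRS >= 2; brute-force check against direct summation
  ipd <- generate_ipd(ipd_generator_spec(n = 1200, seed = 20260101))
  m <- maic(ipd)
  expect_lt(sum(m$weighted_outcome[1:2]), sum(m$unweighted_outcome[1:2]))
  by_hand <- vapply(0:6, function(k) sum(m$weights[ipd$mrs_d90 == k]), numeric(1))
  expect_equal(as.numeric(m$weighted_outcome), by_hand / sum(by_hand),
               tolerance = 1e-12)
})

test_that("weighting the sample toward its own means is an outcome no-op", {
  ipd <- generate_ipd(ipd_generator_spec(n = 600, seed = 9))
  self_targets <- tibble::tibble(
    covariate = c("age", "nihss", "diabetes"),
    type = c("mean", "mean", "proportion"),
    value = c(mean(ipd$age), mean(ipd$nihss), mean(ipd$diabetes))
  )
  m <- maic(ipd, self_targets)
  expect_equal(as.numeric(m$weighted_outcome),
               as.numeric(m$unweighted_outcome), tolerance = 1e-8)
})

test_that("outcome mismatches and degenerate weights are handled", {
  ipd <- toy_ipd()
  expect_error(weighted_outcome_distribution(ipd, rep(1, 3)), "match")
  one_hot <- c(1, rep(0, nrow(ipd) - 1))
  d <- weighted_outcome_distribution(ipd, one_hot)
  expect_equal(unname(d[ipd$mrs_d90[1] + 1]), 1)
})
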