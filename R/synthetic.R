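#' Specification for the synthetic IPD generator
#'
#' Describes a synthetic individual-patient-data table emulating the active
#' (edaravone dexborneol) trial arm: thirteen baseline covariates whose
#' marginals target the trial's published baseline summaries, and a 90-day
#' mRS outcome drawn from a proportional-odds model whose margins are
#' calibrated to the trial's published (pre-adjustment) outcome
#' distribution. Covariate effects on the latent outcome score (NIHSS, age,
#' diabetes by default) make reweighting measurably shift the outcome
#' distribution; setting them to zero yields an outcome independent of the
#' covariates.
#'
#' @param n Number of patients (>= 50); default 1200, the active trial's
#'   enrolment.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param marginals Named list of marginal settings; defaults target the
#'   published baseline column (medians for age/BMI/time-to-treatment/NIHSS,
#'   proportions for the indicators).
#' @param outcome_margins Probability vector over mRS 0..6 targeted by the
#'   outcome model's margins.
#' @param effects Named numeric vector of latent-score effects per unit of
#'   (centred) covariate; positive values push toward worse outcomes.
#' @return An `ipd_generator_spec` list.
#' @export
ipd_generator_spec <- function(n = 1200, seed = 1,
                               marginals = default_ipd_marginals(),
                               outcome_margins = c(0.227, 0.444, 0.128, 0.109,
                                                   0.063, 0.027, 0.000),
                               effects = c(nihss = 0.18, age = 0.02, diabetes = 0.30)) {
  if (n < 50) stop("n must be at least 50", call. = FALSE)
  outcome_margins <- outcome_margins / sum(outcome_margins)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 marginals = marginals, outcome_margins = outcome_margins,
                 effects = effects),
            class = "ipd_generator_spec")
}

#' @rdname ipd_generator_spec
#' @export
default_ipd_marginals <- function() {
  list(
    # continuous: truncated normal, location = published median
    age = list(family = "truncnorm", median = 62.96, sd = 9, lower = 40, upper = 85),
    bmi = list(family = "truncnorm", median = 24.20, sd = 3.1, lower = 15, upper = 40),
    # right-truncated skewed time from onset to treatment (eligibility <= 48 h)
    time_to_treatment = list(family = "scaled_beta", median = 28.0, shape1 = 2.5,
                             lower = 0, upper = 48),
    # severity score on 6..25 (eligibility), geometric decay, median 6
    nihss = list(family = "truncgeom", prob = 0.52, lower = 6, upper = 25),
    male = list(family = "bernoulli", p = 0.6745),
    smoker = list(family = "bernoulli", p = 0.3890),
    previous_stroke = list(family = "bernoulli", p = 0.2905),
    baseline_mrs01 = list(family = "bernoulli", p = 0.9983),
    cardioembolic = list(family = "bernoulli", p = 0.0518),
    hypertension = list(family = "bernoulli", p = 0.6511),
    diabetes = list(family = "bernoulli", p = 0.2521),
    hyperlipidemia = list(family = "bernoulli", p = 0.0735),
    # age-linked via a logistic link so older patients carry more coronary
    # heart disease, preserving the marginal at the published proportion
    chd = list(family = "bernoulli_logit_age", p = 0.0868, slope = 0.04)
  )
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  # inverse-CDF sampling; symmetric truncation keeps the median at `mean`
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic individual-patient-data table
#'
#' Draws the covariates from the spec's marginals (with the mild stated
#' dependencies: coronary heart disease rises with age; the outcome depends
#' on NIHSS, age and diabetes through the latent score), calibrates the
#' proportional-odds cutpoints so the realised linear predictors reproduce
#' the target outcome margins in expectation, and draws the 90-day mRS
#' outcome per patient. Deterministic given the spec (n, seed, settings).
#'
#' @param spec An [ipd_generator_spec()].
#' @return A tibble with the thirteen covariate columns and `mrs_d90`.
#' @export
#' @examples
#' ipd <- generate_ipd(ipd_generator_spec(n = 200, seed = 42))
#' dplyr::count(ipd, mrs_d90)
generate_ipd <- function(spec) {
  stopifnot(inherits(spec, "ipd_generator_spec"))
  n <- spec$n
  m <- spec$marginals
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  draw_marginal <- function(cfg, age = NULL) {
    switch(cfg$family,
      truncnorm = rtruncnorm(n, cfg$median, cfg$sd, cfg$lower, cfg$upper),
      scaled_beta = {
        med <- (cfg$median - cfg$lower) / (cfg$upper - cfg$lower)
        # pbeta(med, a, b) is increasing in b and crosses 0.5 at the b whose
        # beta median equals `med`; pbeta stays accurate at extreme shapes
        shape2 <- stats::uniroot(function(b) stats::pbeta(med, cfg$shape1, b) - 0.5,
                                 c(1e-3, 1e3), tol = 1e-10)$root
        cfg$lower + (cfg$upper - cfg$lower) * stats::rbeta(n, cfg$shape1, shape2)
      },
      truncgeom = {
        k <- cfg$upper - cfg$lower
        pk <- cfg$prob * (1 - cfg$prob)^(0:k)
        cfg$lower + sample(0:k, n, replace = TRUE, prob = pk / sum(pk))
      },
      bernoulli = stats::rbinom(n, 1, cfg$p),
      bernoulli_logit_age = {
        eta <- stats::qlogis(cfg$p) + cfg$slope * (age - mean(age))
        # shift the intercept so the realised marginal stays on target
        shift <- stats::uniroot(function(d) mean(stats::plogis(eta + d)) - cfg$p,
                                c(-5, 5), tol = 1e-10)$root
        stats::rbinom(n, 1, stats::plogis(eta + shift))
      },
      stop("infeasible marginal spec: unknown family ", cfg$family, call. = FALSE)
    )
  }

  age <- draw_marginal(m$age)
  ipd <- tibble::tibble(
    age = age,
    male = draw_marginal(m$male),
    bmi = draw_marginal(m$bmi),
    smoker = draw_marginal(m$smoker),
    time_to_treatment = draw_marginal(m$time_to_treatment),
    previous_stroke = draw_marginal(m$previous_stroke),
    baseline_mrs01 = draw_marginal(m$baseline_mrs01),
    nihss = draw_marginal(m$nihss),
    cardioembolic = draw_marginal(m$cardioembolic),
    hypertension = draw_marginal(m$hypertension),
    diabetes = draw_marginal(m$diabetes),
    hyperlipidemia = draw_marginal(m$hyperlipidemia),
    chd = draw_marginal(m$chd, age = age)
  )

  # proportional-odds outcome: latent score from centred covariates,
  # cutpoints root-found so the sample-average category probabilities
  # reproduce the target margins
  ef <- spec$effects
  eta <- numeric(n)
  for (nm in names(ef)) eta <- eta + ef[[nm]] * (ipd[[nm]] - mean(ipd[[nm]]))
  cum_target <- cumsum(spec$outcome_margins)[1:6]
  cuts <- vapply(cum_target, function(ct) {
    if (ct <= 0) return(-Inf)
    if (ct >= 1) return(Inf)
    stats::uniroot(function(c) mean(stats::plogis(c - eta)) - ct,
                   c(-50, 50), tol = 1e-12)$root
  }, numeric(1))
  cum_probs <- cbind(vapply(cuts, function(c) stats::plogis(c - eta), numeric(n)), 1)
  cell <- cbind(cum_probs[, 1], cum_probs[, -1] - cum_probs[, -7])
  cell[cell < 0] <- 0
  uu <- stats::runif(n)
  ipd$mrs_d90 <- max.col(uu <= t(apply(cell, 1, cumsum)), ties.method = "first") - 1L
  ipd
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Multiplicatively jitter a parameter set
#'
#' Robustness fixture: costs, utilities and hazard ratios receive
#' independent multiplicative noise `U(1 - scale, 1 + scale)`, clipped to
#' their type invariants (utilities to `[0, 1]`, hazard ratios to
#' `>= 1e-6`, costs to `>= 0`). Scale 0 returns the input unchanged.
#'
#' @param params A `stroke_params` object.
#' @param relative_scale Jitter half-width in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return A perturbed `stroke_params`.
#' @export
perturb_params <- function(params, relative_scale, seed) {
  stopifnot(relative_scale >= 0, relative_scale <= 0.5)
  if (relative_scale == 0) return(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jit <- function(x, lo = 0, hi = Inf) {
    pmin(pmax(x * stats::runif(length(x), 1 - relative_scale, 1 + relative_scale), lo), hi)
  }
  params$costs$hospitalization <- jit(params$costs$hospitalization)
  params$costs$post_stroke_annual <- jit(params$costs$post_stroke_annual)
  params$costs$drug$unit_price <- jit(params$costs$drug$unit_price)
  params$utilities$u <- jit(params$utilities$u, 0, 1)
  params$utilities$stroke_disutility <-
    min(jit(params$utilities$stroke_disutility, 0, 1),
        min(params$utilities$u) * 0.999)
  params$mortality$hazard_ratio <- jit(params$mortality$hazard_ratio, 1e-6)
  params
}
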