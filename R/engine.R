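#' Natural (all-cause) annual mortality from the life table
#'
#' Band lookup in the configured life table; ages at or beyond the last band
#' use that band's rate.
#'
#' @param age Age(s) in years; must be at least the model start age.
#' @param params A `stroke_params` object.
#' @return Annual probability of death, vectorised over `age`.
#' @export
#' @examples
#' natural_mortality(60, default_params())
natural_mortality <- function(age, params) {
  if (any(age < params$economics$start_age)) {
    stop("age below model start age ", params$economics$start_age, call. = FALSE)
  }
  lt <- params$mortality$life_table
  idx <- findInterval(age, lt$age_low)
  lt$rate[idx]
}

#' Annual death probability in an alive mRS state
#'
#' Excess post-stroke mortality is expressed as an mRS-state-specific hazard
#' ratio (HR) against the general population. By default the HR acts on the
#' hazard (rate) scale, `p = 1 - (1 - q)^HR`, which keeps the result a valid
#' probability at high ages where the naive product `q * HR` exceeds 1
#' (e.g. age 95, HR 6.55). The multiplicative-probability convention,
#' `min(q * HR, 1)`, is available for calibration via `hr_mode`.
#'
#' @param age Age in years.
#' @param mrs Alive state, integer 0..5 (vectorised).
#' @param params A `stroke_params` object.
#' @param hr_mode `"rate"` (default) or `"probability"`.
#' @return Annual probability of death.
#' @export
#' @examples
#' death_probability(60, 5, default_params())   # ~0.048
death_probability <- function(age, mrs, params, hr_mode = c("rate", "probability")) {
  hr_mode <- match.arg(hr_mode)
  stopifnot(all(mrs %in% 0:5))
  q <- natural_mortality(age, params)
  hr <- unname(params$mortality$hazard_ratio[mrs + 1L])
  if (hr_mode == "rate") 1 - (1 - q)^hr else pmin(q * hr, 1)
}

#' Annual recurrent-stroke probability by model cycle
#'
#' The recurrence risk depends on time since the index stroke: cycle 1 is
#' the first Markov year after the index event. Cycles beyond the last
#' configured year reuse the final ("and above") rate. The risk is assumed
#' identical across alive mRS states.
#'
#' @param cycle Cycle index, integer >= 1 (vectorised).
#' @param params A `stroke_params` object.
#' @return Annual probability of recurrent ischemic stroke.
#' @export
recurrence_probability <- function(cycle, params) {
  stopifnot(all(cycle >= 1))
  rp <- params$recurrence$annual_prob
  rp[pmin(as.integer(cycle), length(rp))]
}

#' Per-cycle 7x7 transition matrix of the Markov cohort model
#'
#' Rows index the origin state (mRS 0..6), columns the destination. Within a
#' cycle, an alive patient first faces the age- and state-specific death
#' probability; survivors face the recurrence risk; recurrent strokes
#' redistribute survivors to equal-or-worse mRS states per the configured
#' redistribution columns, with the per-column remainder dying of the
#' recurrence within the cycle. Death (mRS 6) is absorbing.
#'
#' @param cycle Cycle index >= 1 (sets both age and recurrence risk; the
#'   transition into cycle `k` uses the age at the start of the interval,
#'   `start_age + k - 1`).
#' @param params A `stroke_params` object.
#' @param hr_mode Passed to [death_probability()].
#' @return A row-stochastic 7x7 matrix.
#' @export
build_transition_matrix <- function(cycle, params, hr_mode = c("rate", "probability")) {
  hr_mode <- match.arg(hr_mode)
  stopifnot(cycle >= 1)
  age <- params$economics$start_age + cycle - 1
  pd <- death_probability(age, 0:5, params, hr_mode)
  rk <- recurrence_probability(cycle, params)
  redis <- params$recurrence$redistribution  # [post, pre]
  cf <- params$recurrence$case_fatality
  M <- matrix(0, 7, 7, dimnames = list(paste0("mrs", 0:6), paste0("mrs", 0:6)))
  for (s in 1:6) {
    surv <- 1 - pd[s]
    M[s, 1:6] <- surv * rk * redis[, s]
    M[s, s] <- M[s, s] + surv * (1 - rk)
    M[s, 7] <- pd[s] + surv * rk * cf[s]
  }
  M[7, 7] <- 1
  if (any(M < 0)) stop("negative transition probability: parameter pathology", call. = FALSE)
  M
}

#' Short-term decision-tree stage
#'
#' Distributes patients over 90-day mRS outcomes and prices the acute
#' episode: the arm's full drug-acquisition cost (unit price x units/day x
#' treatment days) plus the one-time hospitalization cost by outcome group
#' (mRS 0-2, 3-5, 6). The 90-day outcome distribution is carried forward to
#' fill the whole first model year, so the first-year quality weight is one
#' year in the 90-day states minus the index-stroke disutility for
#' survivors.
#'
#' @param arm `"edb"` or `"huk"`.
#' @param params A `stroke_params` object.
#' @return A list with `initial` (an [mrs_distribution()]), `drug_cost`,
#'   `hospitalization_cost`, `acute_cost`, and `first_year_qalys`
#'   (undiscounted, before half-cycle weighting).
#' @export
decision_tree_stage <- function(arm, params) {
  if (!arm %in% names(params$d90)) {
    stop("unknown arm: ", arm, " (expected one of ",
         paste(names(params$d90), collapse = ", "), ")", call. = FALSE)
  }
  d90 <- params$d90[[arm]]
  dr <- params$costs$drug[params$costs$drug$arm == arm, ]
  drug_cost <- dr$unit_price * dr$units_per_day * dr$treatment_days
  hosp <- params$costs$hospitalization
  hosp_cost <- sum(d90[1:3]) * hosp[["mrs0_2"]] +
    sum(d90[4:6]) * hosp[["mrs3_5"]] + d90[7] * hosp[["mrs6"]]
  u <- params$utilities$u
  fy <- sum(d90[1:6] * u) - (1 - d90[7]) * params$utilities$stroke_disutility
  list(initial = d90, drug_cost = unname(drug_cost),
       hospitalization_cost = unname(hosp_cost),
       acute_cost = unname(drug_cost + hosp_cost),
       first_year_qalys = unname(fy))
}

#' Propagate the cohort through the Markov model
#'
#' Starting from the arm's 90-day mRS distribution, the state-occupancy
#' vector is propagated through `horizon_cycles` annual transition matrices.
#' Alongside occupancy, the per-cycle recurrence flows needed for event
#' costing are recorded: the mass redistributed to each post-recurrence
#' state and the within-cycle recurrence deaths.
#'
#' @inheritParams decision_tree_stage
#' @param hr_mode Passed to [build_transition_matrix()].
#' @return A `cohort_trace` object: a tibble with columns `cycle`, `age`,
#'   `mrs0`..`mrs6`, plus attributes `recurrence_inflow` (cycle x post-state
#'   matrix of recurrence survivors), `recurrence_deaths` and
#'   `recurrence_survivors` (per-cycle totals).
#' @export
run_cohort <- function(arm, params, hr_mode = c("rate", "probability")) {
  hr_mode <- match.arg(hr_mode)
  n <- params$economics$horizon_cycles
  init <- decision_tree_stage(arm, params)$initial
  occ <- matrix(0, n + 1, 7)
  occ[1, ] <- init
  rec_in <- matrix(0, n + 1, 6)
  rec_dead <- numeric(n + 1)
  redis <- params$recurrence$redistribution
  cf <- params$recurrence$case_fatality
  for (k in seq_len(n)) {
    age <- params$economics$start_age + k - 1
    pd <- death_probability(age, 0:5, params, hr_mode)
    rk <- recurrence_probability(k, params)
    alive <- occ[k, 1:6]
    surv <- alive * (1 - pd)
    recm <- surv * rk                       # mass experiencing recurrence, by origin
    rec_in[k + 1, ] <- as.numeric(redis %*% recm)
    rec_dead[k + 1] <- sum(recm * cf)
    occ[k + 1, 1:6] <- surv * (1 - rk) + rec_in[k + 1, ]
    occ[k + 1, 7] <- occ[k, 7] + sum(alive * pd) + rec_dead[k + 1]
  }
  out <- tibble::as_tibble(as.data.frame(occ))
  names(out) <- paste0("mrs", 0:6)
  out <- dplyr::bind_cols(
    tibble::tibble(cycle = 0:n, age = params$economics$start_age + 0:n), out)
  structure(out,
            recurrence_inflow = rec_in,
            recurrence_deaths = rec_dead,
            recurrence_survivors = rowSums(rec_in),
            arm = arm, hr_mode = hr_mode,
            class = c("cohort_trace", class(out)))
}

#' Accrue discounted costs and QALYs along a cohort trace
#'
#' State-membership quantities (utilities and the index-year post-stroke
#' cost) receive the half-cycle trapezoid weights (1/2 at cycle 0 and the
#' final cycle, 1 elsewhere); one-time event costs (drug, acute
#' hospitalization, recurrence hospitalization) do not. Cycle-`k` accruals
#' are discounted by `(1 + r)^-k`; cycle 0 is undiscounted. The
#' index-stroke disutility is charged once to cycle-0 survivors and the
#' recurrence disutility once per recurrence year to the recurring survivor
#' mass. Post-stroke (secondary-prevention) costs are charged in
#' stroke years: the index year by 90-day outcome group, and each
#' recurrence by post-recurrence group; recurrence deaths incur the mRS-6
#' hospitalization cost.
#'
#' @inheritParams decision_tree_stage
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return An `arm_outcome` list: discounted `qalys`, undiscounted
#'   `life_years`, `cost_total` and components `cost_drug`, `cost_hosp`,
#'   `cost_post`, plus the `trace`.
#' @export
accrue <- function(arm, trace, params) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- params$economics$horizon_cycles
  occ <- as.matrix(trace[, paste0("mrs", 0:6)])
  rec_in <- attr(trace, "recurrence_inflow")
  rec_dead <- attr(trace, "recurrence_deaths")
  rec_surv <- attr(trace, "recurrence_survivors")
  u <- params$utilities$u
  disut <- params$utilities$stroke_disutility
  hosp <- params$costs$hospitalization
  post <- params$costs$post_stroke_annual
  r_out <- params$economics$discount_rate_outcome
  r_cost <- params$economics$discount_rate_cost
  w <- c(0.5, rep(1, n - 1), 0.5)           # half-cycle trapezoid weights
  d_out <- (1 + r_out)^-(0:n)
  d_cost <- (1 + r_cost)^-(0:n)

  tree <- decision_tree_stage(arm, params)

  # QALYs: one year of state utility per cycle, minus stroke-year disutility
  util <- as.numeric(occ[, 1:6] %*% u)
  dis <- c((1 - occ[1, 7]) * disut, rec_surv[-1] * disut)
  qalys <- sum(d_out * w * (util - dis))
  life_years <- sum(w * rowSums(occ[, 1:6]))

  # one-time event costs (no half-cycle weighting)
  cost_drug <- tree$drug_cost
  rec_hosp <- as.numeric(rec_in %*% c(rep(hosp[["mrs0_2"]], 3), rep(hosp[["mrs3_5"]], 3))) +
    rec_dead * hosp[["mrs6"]]
  cost_hosp <- tree$hospitalization_cost + sum(d_cost * rec_hosp)

  # post-stroke secondary-prevention cost: charged in the year of a stroke
  post0 <- sum(occ[1, 1:3]) * post[["mrs0_2"]] + sum(occ[1, 4:6]) * post[["mrs3_5"]]
  rec_post <- as.numeric(rec_in %*% c(rep(post[["mrs0_2"]], 3), rep(post[["mrs3_5"]], 3)))
  cost_post <- w[1] * post0 + sum(d_cost[-1] * rec_post[-1])

  structure(list(
    arm = arm,
    qalys = qalys,
    life_years = life_years,
    cost_drug = cost_drug,
    cost_hosp = cost_hosp,
    cost_post = cost_post,
    cost_total = cost_drug + cost_hosp + cost_post,
    trace = trace
  ), class = "arm_outcome")
}

#' Run one treatment arm end to end
#'
#' Decision tree, cohort propagation and discounted accrual in one call.
#'
#' @inheritParams run_cohort
#' @return An `arm_outcome`; see [accrue()].
#' @export
#' @examples
#' out <- run_arm("edb", default_params())
#' out$qalys
run_arm <- function(arm, params, hr_mode = c("rate", "probability")) {
  trace <- run_cohort(arm, params, hr_mode)
  accrue(arm, trace, params)
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome: %s>\n", x$arm))
  cat(sprintf("  QALYs (discounted): %.3f   life-years: %.2f\n", x$qalys, x$life_years))
  cat(sprintf("  cost: %s = drug %s + hospitalization %s + post-stroke %s\n",
              format(round(x$cost_total), big.mark = ","),
              format(round(x$cost_drug), big.mark = ","),
              format(round(x$cost_hosp), big.mark = ","),
              format(round(x$cost_post), big.mark = ",")))
  invisible(x)
}
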