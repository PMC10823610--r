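#' Construct a probability distribution over mRS states 0--6
#'
#' The modified Rankin Scale (mRS) grades post-stroke disability from 0 (no
#' symptoms) to 5 (severe disability), with 6 denoting death. Model arms are
#' summarised by a probability vector over these seven states.
#'
#' @param p Numeric vector of length 7 (mRS 0..6). Entries must lie in
#'   `[0, 1]`; the vector is renormalised to sum to exactly 1 and an error is
#'   raised if the raw sum deviates from 1 by more than `tol`.
#' @param tol Allowed deviation of `sum(p)` from 1 before normalisation.
#' @return A named numeric vector of class `mrs_distribution`.
#' @export
#' @examples
#' mrs_distribution(c(0.202, 0.406, 0.120, 0.193, 0.048, 0.031, 0))
mrs_distribution <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || length(p) != 7L) {
    stop("`p` must be a numeric vector of length 7 (mRS 0..6)", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("mrs_distribution: entries must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop(sprintf("mrs_distribution: entries sum to %.6f, not 1", s), call. = FALSE)
  }
  out <- p / s
  names(out) <- paste0("mrs", 0:6)
  class(out) <- c("mrs_distribution", "numeric")
  out
}

mrs_group <- function(state) {
  # cost grouping used throughout: mRS 0-2, mRS 3-5, mRS 6 (death)
  ifelse(state <= 2, "mrs0_2", ifelse(state <= 5, "mrs3_5", "mrs6"))
}

#' Load and validate a full model parameter set
#'
#' Reads the structured YAML configuration carrying every model input: the
#' per-arm 90-day mRS distributions, costs (2021 CNY), health-state
#' utilities, natural and excess mortality, recurrent-stroke inputs, economic
#' settings, and the probabilistic / deterministic sensitivity-analysis
#' specifications. Every type invariant is checked and violations are
#' reported with the offending field path.
#'
#' @param path Path to a YAML configuration file; see
#'   `system.file("extdata", "base_case_2021_cny.yaml", package = "strokecea")`
#'   for the packaged base case and its schema.
#' @return A validated parameter bundle of class `stroke_params`.
#' @seealso [default_params()] for the packaged base case,
#'   [write_params()] for the inverse operation.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  params_from_list(raw)
}

#' The packaged base-case parameter set
#'
#' Returns the full parameter bundle of the shipped Chinese healthcare-system
#' base case (2021 CNY): edaravone dexborneol (`edb`, 14-day regimen) versus
#' human urinary kallidinogenase (`huk`, 21-day regimen), MAIC-adjusted
#' 90-day mRS distributions, stroke-registry costs, trial-derived utilities,
#' China life-table mortality with mRS-specific hazard ratios, age-dependent
#' recurrence, 5% annual discounting over a 40-year horizon from age 60, and
#' a willingness-to-pay threshold of 80,976 CNY per QALY.
#'
#' @return A `stroke_params` object.
#' @export
#' @examples
#' p <- default_params()
#' p$utilities$u[["mrs0"]]
default_params <- function() {
  load_params(system.file("extdata", "base_case_2021_cny.yaml",
                          package = "strokecea", mustWork = TRUE))
}

#' Write a parameter set back to a YAML configuration file
#'
#' Inverse of [load_params()]: re-loading the written file yields a
#' field-by-field identical parameter set.
#'
#' @param params A `stroke_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "stroke_params"))
  yaml::write_yaml(params_to_list(params), path, precision = 15)
  invisible(path)
}

# ---- internal construction / validation --------------------------------

fail <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

need <- function(x, key, parent) {
  if (is.null(x[[key]])) fail(paste0(parent, key), "missing key")
  x[[key]]
}

chk_num <- function(x, field, lo = -Inf, hi = Inf, n = 1L) {
  if (!is.numeric(x)) fail(field, "must be numeric")
  if (!is.null(n) && length(x) != n) fail(field, sprintf("must have length %d", n))
  if (any(!is.finite(x))) fail(field, "must be finite")
  if (any(x < lo) || any(x > hi)) {
    fail(field, sprintf("must lie in [%s, %s]", format(lo), format(hi)))
  }
  x
}

params_from_list <- function(raw) {
  d90 <- need(raw, "d90", "")
  arms <- lapply(c(edb = "edb", huk = "huk"), function(a) {
    v <- need(d90, a, "d90/")
    tryCatch(mrs_distribution(as.numeric(v)),
             error = function(e) fail(paste0("d90/", a), conditionMessage(e)))
  })

  split <- need(raw, "initial_split", "")
  s0 <- chk_num(need(split, "mrs0", "initial_split/"), "initial_split/mrs0", 0, 1)
  s1 <- chk_num(need(split, "mrs1", "initial_split/"), "initial_split/mrs1", 0, 1)
  if (abs(s0 + s1 - 1) > 1e-9) fail("initial_split", "mrs0 + mrs1 must sum to 1")

  co <- need(raw, "costs", "")
  drug <- need(co, "drug", "costs/")
  drug_tbl <- purrr::map_dfr(c("edb", "huk"), function(a) {
    d <- need(drug, a, "costs/drug/")
    tibble::tibble(
      arm = a,
      unit_price = chk_num(need(d, "unit_price", "costs/drug/"), paste0("costs/drug/", a, "/unit_price"), 0),
      units_per_day = chk_num(need(d, "units_per_day", "costs/drug/"), paste0("costs/drug/", a, "/units_per_day"), 0),
      treatment_days = chk_num(need(d, "treatment_days", "costs/drug/"), paste0("costs/drug/", a, "/treatment_days"), 0)
    )
  })
  hosp <- need(co, "hospitalization", "costs/")
  hosp_v <- vapply(c("mrs0_2", "mrs3_5", "mrs6"), function(g) {
    chk_num(need(hosp, g, "costs/hospitalization/"), paste0("costs/hospitalization/", g), 0)
  }, numeric(1))
  post <- need(co, "post_stroke_annual", "costs/")
  post_v <- vapply(c("mrs0_2", "mrs3_5"), function(g) {
    chk_num(need(post, g, "costs/post_stroke_annual/"), paste0("costs/post_stroke_annual/", g), 0)
  }, numeric(1))
  hospital_days <- chk_num(need(co, "hospital_days", "costs/"), "costs/hospital_days", 0)

  ut <- need(raw, "utilities", "")
  u <- vapply(paste0("mrs", 0:5), function(k) {
    chk_num(need(ut, k, "utilities/"), paste0("utilities/", k), 0, 1)
  }, numeric(1))
  disut <- chk_num(need(ut, "stroke_disutility", "utilities/"),
                   "utilities/stroke_disutility", 0, 1)
  if (disut >= min(u)) {
    fail("utilities/stroke_disutility",
         "must be smaller than the lowest alive-state utility")
  }

  mo <- need(raw, "mortality", "")
  lt_raw <- need(mo, "life_table", "mortality/")
  life_table <- purrr::map_dfr(lt_raw, function(b) {
    tibble::tibble(
      age_low = chk_num(b$age_low, "mortality/life_table/age_low", 0),
      age_high = as.numeric(b$age_high %||% Inf),
      rate = chk_num(b$rate, "mortality/life_table/rate", 1e-12, 1 - 1e-12)
    )
  })
  if (nrow(life_table) < 1 || is.unsorted(life_table$age_low)) {
    fail("mortality/life_table", "age bands must be present and ordered")
  }
  hr <- chk_num(need(mo, "hazard_ratio", "mortality/"), "mortality/hazard_ratio",
                lo = 0, n = 6L)
  names(hr) <- paste0("mrs", 0:5)

  re <- need(raw, "recurrence", "")
  annual_prob <- chk_num(need(re, "annual_prob", "recurrence/"),
                         "recurrence/annual_prob", 0, 1, n = NULL)
  rd_raw <- need(re, "redistribution", "recurrence/")
  redis <- vapply(paste0("mrs", 0:5), function(k) {
    chk_num(need(rd_raw, k, "recurrence/redistribution/"),
            paste0("recurrence/redistribution/", k), 0, 1, n = 6L)
  }, numeric(6))  # 6x6, column = pre-recurrence state, row = post state
  dimnames(redis) <- list(post = paste0("mrs", 0:5), pre = paste0("mrs", 0:5))
  for (s in 1:6) {
    if (s > 1 && any(redis[seq_len(s - 1), s] > 0)) {
      fail(paste0("recurrence/redistribution/mrs", s - 1),
           "post-recurrence mRS must be >= pre-recurrence mRS")
    }
  }
  case_fatality <- 1 - colSums(redis)
  if (any(case_fatality < -1e-6) || any(case_fatality > 1)) {
    fail("recurrence/redistribution", "column sums must not exceed 1")
  }

  ec <- need(raw, "economics", "")
  econ <- list(
    discount_rate_cost = chk_num(need(ec, "discount_rate_cost", "economics/"),
                                 "economics/discount_rate_cost", 0, 1),
    discount_rate_outcome = chk_num(need(ec, "discount_rate_outcome", "economics/"),
                                    "economics/discount_rate_outcome", 0, 1),
    wtp = chk_num(need(ec, "wtp", "economics/"), "economics/wtp", 0),
    horizon_cycles = as.integer(chk_num(need(ec, "horizon_cycles", "economics/"),
                                        "economics/horizon_cycles", 1)),
    cycle_length = chk_num(need(ec, "cycle_length", "economics/"),
                           "economics/cycle_length", 1, 1),
    start_age = chk_num(need(ec, "start_age", "economics/"), "economics/start_age", 0)
  )

  psa <- purrr::map_dfr(raw$psa %||% list(), function(x) {
    tibble::tibble(parameter = x$parameter, family = x$family,
                   alpha = as.numeric(x$alpha), beta = as.numeric(x$beta))
  })
  if (nrow(psa)) {
    bad <- setdiff(psa$family, c("gamma", "beta", "lognormal", "fixed"))
    if (length(bad)) fail("psa/family", paste("unknown family:", bad[1]))
  }
  dsa <- purrr::map_dfr(raw$dsa %||% list(), function(x) {
    tibble::tibble(parameter = x$parameter,
                   low = as.numeric(x$low), high = as.numeric(x$high))
  })

  params <- structure(list(
    d90 = arms,
    initial_split = c(mrs0 = s0, mrs1 = s1),
    costs = list(drug = drug_tbl, hospital_days = hospital_days,
                 hospitalization = hosp_v, post_stroke_annual = post_v),
    utilities = list(u = u, stroke_disutility = disut),
    mortality = list(life_table = life_table, hazard_ratio = hr),
    recurrence = list(annual_prob = annual_prob, redistribution = redis,
                      case_fatality = case_fatality),
    economics = econ,
    psa = psa,
    dsa = dsa
  ), class = "stroke_params")

  validate_cross(params)
  params
}

validate_cross <- function(params) {
  # PSA specs must reproduce the base value they perturb (gamma mean, beta
  # mean, lognormal median) within 1%, and DSA ranges must bracket the base.
  if (nrow(params$psa)) {
    for (i in seq_len(nrow(params$psa))) {
      row <- params$psa[i, ]
      base <- get_parameter(params, row$parameter)
      centre <- switch(row$family,
        gamma = row$alpha * row$beta,
        beta = row$alpha / (row$alpha + row$beta),
        lognormal = exp(row$alpha),
        fixed = base
      )
      if (abs(centre - base) > 0.01 * max(abs(base), 1e-12)) {
        fail(paste0("psa/", row$parameter),
             sprintf("distribution centre %.4f does not reproduce base value %.4f within 1%%",
                     centre, base))
      }
    }
  }
  if (nrow(params$dsa)) {
    for (i in seq_len(nrow(params$dsa))) {
      row <- params$dsa[i, ]
      base <- get_parameter(params, row$parameter)
      if (row$low > base + 1e-9 || row$high < base - 1e-9) {
        fail(paste0("dsa/", row$parameter),
             sprintf("range [%g, %g] does not bracket base value %g",
                     row$low, row$high, base))
      }
    }
  }
  invisible(params)
}

params_to_list <- function(params) {
  lt <- params$mortality$life_table
  list(
    d90 = list(edb = unname(as.numeric(params$d90$edb)),
               huk = unname(as.numeric(params$d90$huk))),
    initial_split = list(mrs0 = unname(params$initial_split[["mrs0"]]),
                         mrs1 = unname(params$initial_split[["mrs1"]])),
    costs = list(
      drug = stats::setNames(lapply(seq_len(nrow(params$costs$drug)), function(i) {
        r <- params$costs$drug[i, ]
        list(unit_price = r$unit_price, units_per_day = r$units_per_day,
             treatment_days = r$treatment_days)
      }), params$costs$drug$arm),
      hospital_days = params$costs$hospital_days,
      hospitalization = as.list(params$costs$hospitalization),
      post_stroke_annual = as.list(params$costs$post_stroke_annual)
    ),
    utilities = c(as.list(params$utilities$u),
                  list(stroke_disutility = params$utilities$stroke_disutility)),
    mortality = list(
      life_table = lapply(seq_len(nrow(lt)), function(i) {
        list(age_low = lt$age_low[i], age_high = lt$age_high[i], rate = lt$rate[i])
      }),
      hazard_ratio = unname(params$mortality$hazard_ratio)
    ),
    recurrence = list(
      annual_prob = params$recurrence$annual_prob,
      redistribution = stats::setNames(
        lapply(1:6, function(j) unname(params$recurrence$redistribution[, j])),
        paste0("mrs", 0:5))
    ),
    economics = params$economics,
    psa = lapply(seq_len(nrow(params$psa)), function(i) as.list(params$psa[i, ])),
    dsa = lapply(seq_len(nrow(params$dsa)), function(i) as.list(params$dsa[i, ]))
  )
}

# ---- parameter addressing (shared by DSA/PSA) ---------------------------

#' Read a scalar model parameter by identifier
#'
#' Identifiers follow the sensitivity-analysis naming used in the packaged
#' configuration: `u_mrs0`..`u_mrs5`, `stroke_disutility`,
#' `hr_mrs0`..`hr_mrs5`, `cost_hosp_mrs0_2`, `cost_hosp_mrs3_5`,
#' `cost_hosp_mrs6`, `cost_post_mrs0_2`, `cost_post_mrs3_5`,
#' `drug_price_edb`, `drug_price_huk`, `discount_rate_cost`,
#' `discount_rate_outcome`.
#'
#' @param params A `stroke_params` object.
#' @param id Parameter identifier string.
#' @return The scalar base-case value.
#' @export
get_parameter <- function(params, id) {
  if (grepl("^u_mrs[0-5]$", id)) {
    return(unname(params$utilities$u[[sub("^u_", "", id)]]))
  }
  if (id == "stroke_disutility") return(params$utilities$stroke_disutility)
  if (grepl("^hr_mrs[0-5]$", id)) {
    return(unname(params$mortality$hazard_ratio[[sub("^hr_", "", id)]]))
  }
  if (grepl("^cost_hosp_", id)) {
    return(unname(params$costs$hospitalization[[sub("^cost_hosp_", "", id)]]))
  }
  if (grepl("^cost_post_", id)) {
    return(unname(params$costs$post_stroke_annual[[sub("^cost_post_", "", id)]]))
  }
  if (grepl("^drug_price_", id)) {
    arm <- sub("^drug_price_", "", id)
    return(params$costs$drug$unit_price[params$costs$drug$arm == arm])
  }
  if (id %in% c("discount_rate_cost", "discount_rate_outcome")) {
    return(params$economics[[id]])
  }
  stop("unknown parameter id: ", id, call. = FALSE)
}

#' Set a scalar model parameter by identifier
#'
#' @inheritParams get_parameter
#' @param value Replacement value; type invariants (e.g. utilities in
#'   `[0, 1]`) are enforced.
#' @return A modified copy of `params`.
#' @export
set_parameter <- function(params, id, value) {
  value <- as.numeric(value)
  if (grepl("^u_mrs[0-5]$", id)) {
    chk_num(value, id, 0, 1)
    params$utilities$u[[sub("^u_", "", id)]] <- value
  } else if (id == "stroke_disutility") {
    chk_num(value, id, 0, 1)
    params$utilities$stroke_disutility <- value
  } else if (grepl("^hr_mrs[0-5]$", id)) {
    chk_num(value, id, 0)
    params$mortality$hazard_ratio[[sub("^hr_", "", id)]] <- value
  } else if (grepl("^cost_hosp_", id)) {
    chk_num(value, id, 0)
    params$costs$hospitalization[[sub("^cost_hosp_", "", id)]] <- value
  } else if (grepl("^cost_post_", id)) {
    chk_num(value, id, 0)
    params$costs$post_stroke_annual[[sub("^cost_post_", "", id)]] <- value
  } else if (grepl("^drug_price_", id)) {
    chk_num(value, id, 0)
    arm <- sub("^drug_price_", "", id)
    params$costs$drug$unit_price[params$costs$drug$arm == arm] <- value
  } else if (id %in% c("discount_rate_cost", "discount_rate_outcome")) {
    chk_num(value, id, 0, 1)
    params$economics[[id]] <- value
  } else {
    stop("unknown parameter id: ", id, call. = FALSE)
  }
  params
}

#' @export
print.stroke_params <- function(x, ...) {
  cat("<stroke_params>\n")
  cat(sprintf("  arms: %s\n", paste(names(x$d90), collapse = ", ")))
  cat(sprintf("  horizon: %d annual cycles from age %g; discount %g%% (costs) / %g%% (outcomes)\n",
              x$economics$horizon_cycles, x$economics$start_age,
              100 * x$economics$discount_rate_cost,
              100 * x$economics$discount_rate_outcome))
  cat(sprintf("  WTP: %s CNY/QALY; %d PSA distributions, %d DSA ranges\n",
              format(x$economics$wtp, big.mark = ","), nrow(x$psa), nrow(x$dsa)))
  invisible(x)
}

`%||%` <- rlang::`%||%`
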