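#' One-way deterministic sensitivity analysis (tornado data)
#'
#' For each configured parameter range, the model is re-run for both arms
#' with the parameter at its lower and upper bound (all others at base
#' case), and the resulting ICER and incremental NMB recorded. Rows are
#' sorted by ICER span (|high - low|) descending, the order of a tornado
#' diagram. Ranges that violate a type invariant are skipped with a
#' warning.
#'
#' @param params A `stroke_params` object.
#' @param wtp Willingness-to-pay threshold.
#' @param hr_mode Mortality convention, see [death_probability()].
#' @return A `stroke_dsa` tibble: `parameter`, `base`, `low`, `high`,
#'   `icer_base`, `icer_low`, `icer_high`, `inmb_low`, `inmb_high`, `span`.
#' @export
#' @examples
#' \donttest{
#' dsa <- run_dsa(default_params())
#' head(dsa, 3)
#' }
run_dsa <- function(params, wtp = params$economics$wtp,
                    hr_mode = c("rate", "probability")) {
  hr_mode <- match.arg(hr_mode)
  if (!nrow(params$dsa)) stop("no DSA ranges configured", call. = FALSE)
  base_glance <- glance(run_base_case(params, wtp, hr_mode))
  eval_at <- function(id, value) {
    p <- tryCatch(set_parameter(params, id, value), error = function(e) e)
    if (inherits(p, "error")) return(NULL)
    glance(run_base_case(p, wtp, hr_mode))
  }
  rows <- purrr::pmap(params$dsa, function(parameter, low, high) {
    lo <- eval_at(parameter, low)
    hi <- eval_at(parameter, high)
    if (is.null(lo) || is.null(hi)) {
      warning("skipping DSA range for ", parameter, ": invariant violation",
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      parameter = parameter, base = get_parameter(params, parameter),
      low = low, high = high,
      icer_base = base_glance$icer, icer_low = lo$icer, icer_high = hi$icer,
      inmb_low = lo$incremental_nmb, inmb_high = hi$incremental_nmb,
      span = abs(hi$icer - lo$icer)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$span))
  structure(out, wtp = wtp, class = c("stroke_dsa", class(out)))
}

#' Draw one probabilistic parameter set
#'
#' Each parameter with a sampling distribution is drawn independently from
#' it -- gamma (shape, scale) for costs, beta (shape1, shape2) for utilities
#' and the stroke disutility, lognormal (meanlog, sdlog) for hazard ratios.
#' Parameters without a distribution (drug prices, discount rates, the
#' 90-day outcome distributions) keep their base value. Uses the current
#' RNG state; seed control belongs to the caller (see [run_psa()]).
#'
#' @param params A `stroke_params` object.
#' @return A modified `stroke_params` draw.
#' @export
sample_parameter_set <- function(params) {
  spec <- params$psa
  if (!nrow(spec)) return(params)
  draws <- purrr::pmap_dbl(spec, function(parameter, family, alpha, beta) {
    switch(family,
      gamma = stats::rgamma(1, shape = alpha, scale = beta),
      beta = stats::rbeta(1, shape1 = alpha, shape2 = beta),
      lognormal = stats::rlnorm(1, meanlog = alpha, sdlog = beta),
      fixed = get_parameter(params, parameter)
    )
  })
  for (i in seq_along(draws)) {
    params <- set_parameter_unchecked(params, spec$parameter[i], draws[i])
  }
  params
}

# PSA draws may transiently break cross-parameter invariants (e.g. drawn
# utilities need not stay monotone in mRS and a drawn disutility may exceed
# the smallest utility); marginals are sampled independently by design, so
# bypass the cross checks that set_parameter applies to user edits.
set_parameter_unchecked <- function(params, id, value) {
  if (grepl("^u_mrs[0-5]$", id)) {
    params$utilities$u[[sub("^u_", "", id)]] <- value
  } else if (id == "stroke_disutility") {
    params$utilities$stroke_disutility <- value
  } else {
    params <- set_parameter(params, id, value)
  }
  params
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws `n_iter` parameter sets from the configured distributions and
#' evaluates both arms under the *same* draw (arms differ only in their
#' 90-day outcome distribution and drug cost, so shared draws do not create
#' spurious between-arm differences). Produces the cost-effectiveness plane
#' (per-iteration incremental cost and QALYs) and the cost-effectiveness
#' acceptability curve (CEAC): the probability of a positive incremental
#' NMB across a willingness-to-pay grid.
#'
#' @param params A `stroke_params` object.
#' @param n_iter Number of Monte Carlo iterations (>= 1).
#' @param seed Integer seed; results are fully reproducible given it.
#' @param wtp_grid Thresholds for the CEAC; defaults to 0 to three times the
#'   configured threshold in 1,000-CNY steps, always including the
#'   configured threshold itself.
#' @param hr_mode Mortality convention, see [death_probability()].
#' @return A `stroke_psa` object: `draws` (tibble with `iteration`,
#'   `dcost`, `dqalys`, `icer`), `ceac` (tibble `wtp`, `probability`),
#'   `p_ce_at_wtp` (probability cost-effective at the configured
#'   threshold), `wtp`, `seed`, `n_iter`.
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(default_params(), n_iter = 100, seed = 1)
#' psa$p_ce_at_wtp
#' }
run_psa <- function(params, n_iter = 1000, seed,
                    wtp_grid = NULL, hr_mode = c("rate", "probability")) {
  hr_mode <- match.arg(hr_mode)
  stopifnot(n_iter >= 1)
  if (missing(seed)) stop("an explicit `seed` is required for reproducibility", call. = FALSE)
  wtp <- params$economics$wtp
  if (is.null(wtp_grid)) {
    wtp_grid <- sort(unique(c(seq(0, 3 * wtp, by = 1000), wtp)))
  }
  set.seed(seed)
  draws <- purrr::map_dfr(seq_len(n_iter), function(i) {
    p <- sample_parameter_set(params)
    e <- run_arm("edb", p, hr_mode)
    h <- run_arm("huk", p, hr_mode)
    tibble::tibble(iteration = i,
                   dcost = e$cost_total - h$cost_total,
                   dqalys = e$qalys - h$qalys)
  })
  draws$icer <- ifelse(draws$dqalys == 0, NA_real_, draws$dcost / draws$dqalys)
  inmb <- outer(draws$dqalys, wtp_grid) - draws$dcost
  ceac <- tibble::tibble(wtp = wtp_grid, probability = colMeans(inmb > 0))
  structure(list(
    draws = draws,
    ceac = ceac,
    p_ce_at_wtp = mean(draws$dqalys * wtp - draws$dcost > 0),
    wtp = wtp, seed = seed, n_iter = n_iter
  ), class = "stroke_psa")
}

#' @rdname run_psa
#' @param x A `stroke_psa` object.
#' @param ... Unused.
#' @return `tidy()`: the per-iteration cost-effectiveness-plane tibble.
#' @exportS3Method
tidy.stroke_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @return `glance()`: a one-row tibble with mean increments, the mean ICER
#'   of means, and the probability cost-effective at the threshold.
#' @exportS3Method
glance.stroke_psa <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter, seed = x$seed,
    mean_dcost = mean(x$draws$dcost),
    mean_dqalys = mean(x$draws$dqalys),
    icer_of_means = mean(x$draws$dcost) / mean(x$draws$dqalys),
    p_ce_at_wtp = x$p_ce_at_wtp, wtp = x$wtp
  )
}

#' @export
print.stroke_psa <- function(x, ...) {
  cat(sprintf("<stroke_psa: %d iterations, seed %s>\n", x$n_iter, format(x$seed)))
  cat(sprintf("  mean incremental: %.4f QALYs, %s CNY\n",
              mean(x$draws$dqalys), format(round(mean(x$draws$dcost)), big.mark = ",")))
  cat(sprintf("  P(cost-effective at %s CNY/QALY) = %.3f\n",
              format(x$wtp, big.mark = ","), x$p_ce_at_wtp))
  invisible(x)
}
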