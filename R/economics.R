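#' Compare two arm outcomes: ICER and net monetary benefit
#'
#' Computes incremental discounted cost and QALYs of the intervention versus
#' the comparator, the incremental cost-effectiveness ratio (ICER,
#' incremental cost per QALY gained), and per-arm and incremental net
#' monetary benefit (NMB = QALYs x WTP - cost) at the willingness-to-pay
#' threshold. Dominance quadrants are flagged instead of reporting a
#' misleading finite ICER: `"dominant"` (cheaper and more effective),
#' `"dominated"` (dearer and less effective), `"undefined"` (no QALY
#' difference). All statistics are computed at full precision; rounding is
#' left to the reporting layer.
#'
#' @param intervention,comparator `arm_outcome` objects from [run_arm()].
#' @param wtp Willingness-to-pay threshold (currency per QALY).
#' @return A `cea_result` list with per-arm costs/QALYs/NMB, increments,
#'   `icer`, and `icer_status` (`"ok"`, `"dominant"`, `"dominated"`,
#'   `"undefined"`).
#' @export
#' @examples
#' p <- default_params()
#' compare_arms(run_arm("edb", p), run_arm("huk", p), wtp = p$economics$wtp)
compare_arms <- function(intervention, comparator, wtp) {
  stopifnot(inherits(intervention, "arm_outcome"), inherits(comparator, "arm_outcome"))
  dq <- intervention$qalys - comparator$qalys
  dc <- intervention$cost_total - comparator$cost_total
  status <- if (dq == 0) {
    "undefined"
  } else if (dq > 0 && dc < 0) {
    "dominant"
  } else if (dq < 0 && dc > 0) {
    "dominated"
  } else {
    "ok"
  }
  icer <- if (status == "ok") dc / dq else NA_real_
  nmb_i <- intervention$qalys * wtp - intervention$cost_total
  nmb_c <- comparator$qalys * wtp - comparator$cost_total
  structure(list(
    intervention = intervention$arm, comparator = comparator$arm,
    cost = c(stats::setNames(intervention$cost_total, intervention$arm),
             stats::setNames(comparator$cost_total, comparator$arm)),
    qalys = c(stats::setNames(intervention$qalys, intervention$arm),
              stats::setNames(comparator$qalys, comparator$arm)),
    incremental_cost = dc,
    incremental_qalys = dq,
    icer = icer,
    icer_status = status,
    nmb = c(stats::setNames(nmb_i, intervention$arm),
            stats::setNames(nmb_c, comparator$arm)),
    incremental_nmb = dq * wtp - dc,
    wtp = wtp,
    arms = list(intervention = intervention, comparator = comparator)
  ), class = "cea_result")
}

#' Run the full base-case comparison
#'
#' Both arms through the decision tree, Markov cohort and accrual, then
#' [compare_arms()] at the configured threshold.
#'
#' @param params A `stroke_params` object (default: packaged base case).
#' @param wtp Willingness-to-pay threshold; defaults to the configured one.
#' @param hr_mode Mortality hazard-ratio convention, see [death_probability()].
#' @return A `cea_result`.
#' @export
run_base_case <- function(params = default_params(), wtp = params$economics$wtp,
                          hr_mode = c("rate", "probability")) {
  hr_mode <- match.arg(hr_mode)
  compare_arms(run_arm("edb", params, hr_mode), run_arm("huk", params, hr_mode), wtp)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost-effectiveness comparison into a report table
#'
#' One row per reporting quantity (QALYs, cost components, NMB, increments,
#' ICER), one column per arm plus an `incremental` column, mirroring the
#' usual base-case results table of a trial-based economic evaluation.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method
tidy.cea_result <- function(x, ...) {
  i <- x$arms$intervention
  c_ <- x$arms$comparator
  tibble::tibble(
    quantity = c("qalys", "cost_total", "cost_drug", "cost_hosp", "cost_post",
                 "nmb", "icer"),
    !!x$intervention := c(i$qalys, i$cost_total, i$cost_drug, i$cost_hosp,
                          i$cost_post, unname(x$nmb[x$intervention]), NA),
    !!x$comparator := c(c_$qalys, c_$cost_total, c_$cost_drug, c_$cost_hosp,
                        c_$cost_post, unname(x$nmb[x$comparator]), NA),
    incremental = c(x$incremental_qalys, x$incremental_cost,
                    i$cost_drug - c_$cost_drug, i$cost_hosp - c_$cost_hosp,
                    i$cost_post - c_$cost_post, x$incremental_nmb, x$icer)
  )
}

#' One-line summary of a cost-effectiveness comparison
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A one-row tibble with increments, ICER, status and threshold.
#' @exportS3Method
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    incremental_cost = x$incremental_cost,
    incremental_qalys = x$incremental_qalys,
    icer = x$icer,
    icer_status = x$icer_status,
    incremental_nmb = x$incremental_nmb,
    wtp = x$wtp
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result: %s vs %s>\n", x$intervention, x$comparator))
  cat(sprintf("  incremental: %.4f QALYs, %s CNY\n", x$incremental_qalys,
              format(round(x$incremental_cost), big.mark = ",")))
  if (x$icer_status == "ok") {
    cat(sprintf("  ICER: %s CNY/QALY (WTP %s)\n",
                format(round(x$icer), big.mark = ","),
                format(x$wtp, big.mark = ",")))
  } else {
    cat(sprintf("  ICER: %s\n", x$icer_status))
  }
  cat(sprintf("  incremental NMB: %s CNY\n",
              format(round(x$incremental_nmb), big.mark = ",")))
  invisible(x)
}
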