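#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICER at each parameter's lower and upper
#' bound, widest span on top, with the base-case ICER as a reference line.
#'
#' @param object A `stroke_dsa` from [run_dsa()].
#' @param top Number of parameters to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.stroke_dsa <- function(object, top = nrow(object), ...) {
  df <- utils::head(object, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = df$icer_base[1], linetype = 2) +
    ggplot2::labs(x = "ICER (CNY per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane of the probabilistic sensitivity analysis
#'
#' Per-iteration incremental cost against incremental QALYs, with the
#' willingness-to-pay threshold as a line through the origin.
#'
#' @param object A `stroke_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.stroke_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws, ggplot2::aes(.data$dqalys, .data$dcost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = object$wtp, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of a positive incremental net monetary benefit as a function
#' of the willingness-to-pay threshold.
#'
#' @param psa A `stroke_psa` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  stopifnot(inherits(psa, "stroke_psa"))
  ggplot2::ggplot(psa$ceac, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = psa$wtp, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CNY per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' State-occupancy area plot of a cohort trace
#'
#' @param object A `cohort_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::starts_with("mrs"),
                              names_to = "state", values_to = "occupancy")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "Cycle (years)", y = "State occupancy",
                  title = "Markov cohort trace") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
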