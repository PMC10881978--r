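#' Plot an operating-point cloud as a ROC scatter
#'
#' @param object An `operating_points` tibble from
#'   [sweep_operating_points()].
#' @param ... Unused.
#' @return A ggplot: sensitivity against 1 - specificity, coloured by
#'   threshold-adjustment step, with the status-quo point highlighted.
#' @export
autoplot.operating_points <- function(object, ...) {
  sq <- select_status_quo(object)
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$step), alpha = 0.4,
                        size = 0.8) +
    ggplot2::geom_point(data = sq, colour = "black", shape = 8, size = 3) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Threshold step",
                  title = "Operating points of the grade-level threshold sweep") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness frontier
#'
#' @param object A [cea_frontier()] object.
#' @param per_person Divide costs and effects by this population size for
#'   display (default 1: totals).
#' @param ... Unused.
#' @return A ggplot of the cost-effect plane with dominance labels and the
#'   frontier path.
#' @export
autoplot.cea_frontier <- function(object, per_person = 1, ...) {
  s <- object$scenarios
  s$cost_d <- s$cost / per_person
  s$effect_d <- s$effect / per_person
  fr <- s[match(object$frontier, s$scenario_id), ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$effect_d, y = .data$cost_d)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.6) +
    ggplot2::geom_path(data = fr, colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "Effect (QALYs)", y = "Cost (US$)", colour = NULL,
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("WTP %s US$/QALY",
                                     format(object$wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param object A [run_psa()] object.
#' @param ... Unused.
#' @return A ggplot: per scenario, the probability of being the
#'   NMB-optimal choice across willingness-to-pay levels.
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = factor(.data$scenario_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (US$/QALY)",
                  y = "Probability cost-effective", colour = "Scenario",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param object A [univariate_sweep()] result.
#' @param ... Unused.
#' @return A ggplot: per parameter, the range of the best cost-effective
#'   scenario's net monetary benefit across the low/high perturbations,
#'   widest effects on top.
#' @export
autoplot.tornado_analysis <- function(object, ...) {
  base_nmb <- attr(object, "base")$nmb
  d <- dplyr::mutate(
    object,
    lo = pmin(.data$nmb_low, .data$nmb_high),
    hi = pmax(.data$nmb_low, .data$nmb_high),
    span = .data$hi - .data$lo
  )
  d$parameter <- stats::reorder(d$parameter, d$span)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_nmb, linetype = "dashed") +
    ggplot2::labs(x = "Net monetary benefit of the BCES (US$)", y = NULL,
                  title = "Univariate sensitivity of the cost-effectiveness ranking") +
    ggplot2::theme_minimal()
}
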