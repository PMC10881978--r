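#' Tidy a cost-effectiveness frontier
#'
#' @param x A [cea_frontier()] object.
#' @param ... Unused.
#' @return The per-scenario tibble with dominance labels, frontier ICERs
#'   and (when a status quo was given) ICER and NMB against it.
#' @export
tidy.cea_frontier <- function(x, ...) {
  x$scenarios
}

#' One-row summary of a cost-effectiveness frontier
#'
#' @param x A [cea_frontier()] object.
#' @param ... Unused.
#' @return Tibble with scenario counts per label, the BCES id and the WTP.
#' @export
glance.cea_frontier <- function(x, ...) {
  s <- x$scenarios
  tibble::tibble(
    n_scenarios = nrow(s),
    n_frontier = sum(s$on_frontier),
    n_dominated = sum(s$label == "dominated"),
    n_extended_dominated = sum(s$label == "extended_dominated"),
    n_above_wtp = sum(s$label == "above_wtp"),
    bces_id = x$bces_id %||% NA,
    wtp = x$wtp
  )
}

#' Tidy a cohort-model run
#'
#' @param x A [run_cohort()] object.
#' @param ... Unused.
#' @return The Markov trace in long form: `cycle`, `state`,
#'   `expected_persons`, plus the per-cycle discounted accruals repeated by
#'   state.
#' @export
tidy.cohort_run <- function(x, ...) {
  if (is.null(x$trace)) {
    stop("run_cohort() was called with keep_trace = FALSE", call. = FALSE)
  }
  tidyr::pivot_longer(x$trace, dplyr::all_of(.STATE_NAMES),
                      names_to = "state", values_to = "expected_persons")
}

#' One-row summary of a cohort-model run
#'
#' @param x A [run_cohort()] object.
#' @param ... Unused.
#' @return The result row: operating point, discounted per-person and total
#'   cost and QALYs.
#' @export
glance.cohort_run <- function(x, ...) {
  x$result
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A [run_psa()] object.
#' @param ... Unused.
#' @return The cost-effectiveness acceptability curve: `wtp`,
#'   `scenario_id`, `probability`.
#' @export
tidy.psa_result <- function(x, ...) {
  x$ceac
}

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A [run_psa()] object.
#' @param ... Unused.
#' @return Tibble with draw counts and the scenario most often optimal at
#'   the highest WTP evaluated.
#' @export
glance.psa_result <- function(x, ...) {
  top <- dplyr::slice_max(
    dplyr::filter(x$ceac, .data$wtp == max(.data$wtp)),
    .data$probability, n = 1, with_ties = FALSE
  )
  tibble::tibble(
    n_sims = x$n_sims,
    n_scenarios = nrow(x$summaries),
    n_resampled = x$n_resampled,
    top_scenario = top$scenario_id,
    top_probability = top$probability
  )
}

#' @export
print.cea_frontier <- function(x, ...) {
  g <- glance(x)
  cat("<cea_frontier>", g$n_scenarios, "scenarios,", g$n_frontier,
      "on the frontier (WTP", format(x$wtp, big.mark = ","), "US$/QALY)\n")
  cat("  dominated:", g$n_dominated,
      " extended dominated:", g$n_extended_dominated,
      " above WTP:", g$n_above_wtp, "\n")
  if (!is.null(x$bces_id)) cat("  best cost-effective scenario:", x$bces_id,
                               "\n")
  invisible(x)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_sims, "Monte-Carlo draws,",
      nrow(x$summaries), "scenarios,", length(x$wtps), "WTP levels\n")
  invisible(x)
}
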