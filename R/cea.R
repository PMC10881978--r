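#' Incremental cost-effectiveness ratio
#'
#' `ICER = incremental cost / QALYs gained`, on the natural scale
#' (US$ per QALY). A zero incremental effect leaves the ICER undefined:
#' `NA` is returned and the caller must fall back on dominance logic rather
#' than divide.
#'
#' @param incr_cost Incremental cost (US$).
#' @param incr_effect Incremental effect (QALYs).
#' @return US$ per QALY, or `NA` where `incr_effect` is zero.
#' @examples
#' icer(14834000, 839) # 17681
#' @export
icer <- function(incr_cost, incr_effect) {
  out <- ifelse(incr_effect == 0, NA_real_, incr_cost / incr_effect)
  as.numeric(out)
}

#' Net monetary benefit
#'
#' `NMB = incremental effect x WTP - incremental cost` (US$).
#'
#' @param incr_effect Incremental effect (QALYs).
#' @param incr_cost Incremental cost (US$).
#' @param wtp Willingness-to-pay threshold (US$/QALY).
#' @return US$.
#' @examples
#' nmb(839, 14834000, 30828) # 11,030,692
#' @export
nmb <- function(incr_effect, incr_cost, wtp) {
  incr_effect * wtp - incr_cost
}

#' Predictive values and expected confusion counts of an operating point
#'
#' Bayes' rule applied to a screening test: positive predictive value
#' `PPV = p se / (p se + (1 - p)(1 - sp))` and negative predictive value
#' `NPV = (1 - p) sp / ((1 - p) sp + p (1 - se))`, plus expected confusion
#' counts when a population size is supplied.
#'
#' @param sensitivity,specificity Test operating point.
#' @param prevalence Disease prevalence.
#' @param n Optional population size for expected counts.
#' @return One-row tibble with `ppv`, `npv` and (when `n` is given)
#'   `e_tp`, `e_fp`, `e_tn`, `e_fn`. A predictive value with a zero
#'   denominator is `NA`.
#' @examples
#' diagnostic_metrics(0.933, 0.877, 0.08) # ppv 0.397, npv 0.993
#' @export
diagnostic_metrics <- function(sensitivity, specificity, prevalence,
                               n = NULL) {
  check_scalar_prob(sensitivity, "sensitivity")
  check_scalar_prob(specificity, "specificity")
  check_scalar_prob(prevalence, "prevalence")
  p <- prevalence
  den_pos <- p * sensitivity + (1 - p) * (1 - specificity)
  den_neg <- (1 - p) * specificity + p * (1 - sensitivity)
  out <- tibble::tibble(
    ppv = ifelse(den_pos == 0, NA_real_, p * sensitivity / den_pos),
    npv = ifelse(den_neg == 0, NA_real_, (1 - p) * specificity / den_neg)
  )
  if (!is.null(n)) {
    check_scalar_nonneg(n, "n")
    out$e_tp <- n * p * sensitivity
    out$e_fn <- n * p * (1 - sensitivity)
    out$e_tn <- n * (1 - p) * specificity
    out$e_fp <- n * (1 - p) * (1 - specificity)
  }
  out
}

.op_se_sp <- function(op, what) {
  if (is.data.frame(op)) {
    c(op$sensitivity[1], op$specificity[1])
  } else if (is.numeric(op) && length(op) == 2L) {
    as.numeric(op)
  } else if (is.list(op)) {
    c(op$sensitivity, op$specificity)
  } else {
    stop("`", what, "` must supply sensitivity and specificity",
         call. = FALSE)
  }
}

#' Expected change in false positives and false negatives between two
#' operating points
#'
#' Moving from operating point `op_a` to `op_b` in a population of size `n`
#' at the given prevalence changes the expected error counts by
#' `increase_fp = n (1 - p)(sp_a - sp_b)` and
#' `decrease_fn = n p (se_b - se_a)`.
#'
#' @param op_a,op_b Operating points: one-row tibbles, lists with
#'   `sensitivity`/`specificity`, or `c(sensitivity, specificity)` pairs.
#' @param prevalence Disease prevalence.
#' @param n Population size.
#' @return One-row tibble with `increase_fp` and `decrease_fn`.
#' @examples
#' delta_counts(c(0.933, 0.877), c(0.963, 0.804), 0.08, 251535)
#' @export
delta_counts <- function(op_a, op_b, prevalence, n) {
  a <- .op_se_sp(op_a, "op_a"); b <- .op_se_sp(op_b, "op_b")
  check_scalar_prob(prevalence, "prevalence")
  check_scalar_nonneg(n, "n")
  tibble::tibble(
    increase_fp = n * (1 - prevalence) * (a[2] - b[2]),
    decrease_fn = n * prevalence * (b[1] - a[1])
  )
}

.frontier_scenarios <- function(scenarios) {
  s <- tibble::as_tibble(scenarios)
  if (!"cost" %in% names(s) && "total_cost" %in% names(s)) {
    s$cost <- s$total_cost
  }
  if (!"effect" %in% names(s) && "total_qaly" %in% names(s)) {
    s$effect <- s$total_qaly
  }
  if (!all(c("cost", "effect") %in% names(s))) {
    stop("`scenarios` must have cost/effect (or total_cost/total_qaly) ",
         "columns", call. = FALSE)
  }
  if (!"scenario_id" %in% names(s)) s$scenario_id <- seq_len(nrow(s))
  s
}

#' Cost-effectiveness frontier with dominance and extended dominance
#'
#' Implements the standard scenario-selection workflow: (1) remove strictly
#' dominated scenarios (at least as costly and no more effective than
#' another, with one inequality strict); (2) remove extended-dominated
#' scenarios (those whose incremental ICER against the previous frontier
#' member exceeds that of a later member), iterating until the frontier
#' ICER sequence strictly increases; (3) remove scenarios whose frontier
#' ICER exceeds the willingness-to-pay threshold. Scenarios with identical
#' cost and effect (duplicate operating points) share the fate of their
#' representative. Survivors are labelled against the status quo:
#' `cost_saving` when strictly cheaper, `cost_effective` otherwise.
#'
#' @param scenarios Tibble with `cost` and `effect` columns (`total_cost` /
#'   `total_qaly` are accepted aliases), optionally `scenario_id`; typically
#'   the output of [run_scenarios()].
#' @param wtp Willingness-to-pay threshold (US$/QALY).
#' @param status_quo Optional `scenario_id` of the comparison baseline. When
#'   given, survivor labels and the `icer_vs_status_quo` / `nmb` columns are
#'   computed against it.
#'
#' @return An object of class `cea_frontier`: a list with
#'   * `scenarios`: the input plus `label` (one of `dominated`,
#'     `extended_dominated`, `above_wtp`, `cost_saving`, `cost_effective`,
#'     `status_quo`), `on_frontier`, `icer_vs_prev` (along the frontier),
#'     and, when a status quo is given, `icer_vs_status_quo` and `nmb`;
#'   * `frontier`: survivor `scenario_id`s ordered by increasing effect;
#'   * `bces_id`: the best cost-effective scenario (maximum effect among
#'     survivors, ties to the lower cost);
#'   * `wtp`, `status_quo`.
#' @examples
#' s <- tibble::tibble(scenario_id = c("A", "B", "C"),
#'                     cost = c(0, 100, 110), effect = c(0, 1, 2))
#' fr <- cea_frontier(s, wtp = 1000)
#' tidy(fr)$label # B is extended-dominated
#' @export
cea_frontier <- function(scenarios, wtp, status_quo = NULL) {
  check_scalar_nonneg(wtp, "wtp")
  s <- .frontier_scenarios(scenarios)
  if (nrow(s) < 1L) stop("`scenarios` is empty", call. = FALSE)
  if (!is.null(status_quo) && !status_quo %in% s$scenario_id) {
    stop("`status_quo` is not a scenario_id of `scenarios`", call. = FALSE)
  }

  # collapse exact (cost, effect) duplicates onto one representative
  key <- paste(s$cost, s$effect)
  rep_row <- match(key, key)
  uniq <- which(rep_row == seq_len(nrow(s)))
  cost <- s$cost[uniq]; eff <- s$effect[uniq]
  m <- length(uniq)
  lab <- rep(NA_character_, m)

  # strict dominance (pairwise, O(m^2))
  dominated <- vapply(seq_len(m), function(i) {
    any(cost <= cost[i] & eff >= eff[i] &
          (cost < cost[i] | eff > eff[i]))
  }, logical(1))
  lab[dominated] <- "dominated"

  # extended dominance: walk the survivors by increasing effect and remove
  # members breaking the increasing-ICER sequence, to a fixed point
  cand <- which(!dominated)
  cand <- cand[order(eff[cand], cost[cand])]
  repeat {
    if (length(cand) < 3L) break
    ic <- diff(cost[cand]) / diff(eff[cand])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    lab[cand[bad[1L] + 1L]] <- "extended_dominated"
    cand <- cand[-(bad[1L] + 1L)]
  }

  # willingness-to-pay rule: frontier ICERs now increase, so the first
  # breach truncates the frontier
  ic_prev <- rep(NA_real_, m)
  if (length(cand) > 1L) {
    ic_prev[cand[-1L]] <- diff(cost[cand]) / diff(eff[cand])
  }
  breach <- which(!is.na(ic_prev[cand]) & ic_prev[cand] > wtp)
  if (length(breach)) {
    lab[cand[breach[1L]:length(cand)]] <- "above_wtp"
    cand <- cand[seq_len(breach[1L] - 1L)]
  }
  lab[cand] <- "cost_effective"

  # propagate representative labels to duplicates, then map back to rows
  label <- lab[match(rep_row, uniq)]
  on_frontier <- label == "cost_effective"
  icer_vs_prev <- ic_prev[match(rep_row, uniq)]
  icer_vs_prev[!on_frontier] <- NA_real_

  s$label <- label
  s$on_frontier <- on_frontier
  s$icer_vs_prev <- icer_vs_prev

  if (!is.null(status_quo)) {
    sq <- match(status_quo, s$scenario_id)
    s$icer_vs_status_quo <- icer(s$cost - s$cost[sq], s$effect - s$effect[sq])
    s$nmb <- nmb(s$effect - s$effect[sq], s$cost - s$cost[sq], wtp)
    s$label[s$on_frontier & s$cost < s$cost[sq]] <- "cost_saving"
    if (s$on_frontier[sq]) s$label[sq] <- "status_quo"
  }

  surv <- s$label %in% c("cost_effective", "cost_saving", "status_quo")
  ord <- order(s$effect, s$cost)
  frontier_ids <- s$scenario_id[ord][surv[ord]]
  bces_id <- select_bces_ids(s)

  structure(
    list(scenarios = s, frontier = frontier_ids, bces_id = bces_id,
         wtp = wtp, status_quo = status_quo),
    class = "cea_frontier"
  )
}

# internal: max-effect survivor, ties to the lower cost then first id
select_bces_ids <- function(s) {
  elig <- which(s$label %in% c("cost_effective", "cost_saving", "status_quo"))
  if (!length(elig)) return(NULL)
  best <- elig[order(-s$effect[elig], s$cost[elig])][1L]
  s$scenario_id[best]
}

#' Select the best cost-effective scenario
#'
#' The best cost-effective scenario (BCES) is the frontier survivor with
#' maximum effect; ties go to the lower cost.
#'
#' @param frontier_result A [cea_frontier()] object.
#' @return The `scenario_id` of the BCES, or an error when no scenario
#'   survives the frontier rules.
#' @export
select_bces <- function(frontier_result) {
  stopifnot(inherits(frontier_result, "cea_frontier"))
  if (is.null(frontier_result$bces_id)) {
    stop("no scenario survives the frontier rules", call. = FALSE)
  }
  frontier_result$bces_id
}

#' Classify a scenario against the status quo
#'
#' A surviving scenario is `cost_saving` when it costs less than the status
#' quo, `cost_effective` when it costs at least as much and its ICER against
#' the status quo does not exceed the willingness-to-pay threshold, and
#' `"neither"` otherwise.
#'
#' @param scenario,status_quo Lists/rows with `cost` and `effect` (aliases
#'   `total_cost`/`total_qaly` accepted).
#' @param wtp Willingness-to-pay threshold (US$/QALY).
#' @return One of `"cost_saving"`, `"cost_effective"`, `"neither"`.
#' @export
classify_vs_status_quo <- function(scenario, status_quo, wtp) {
  get_ce <- function(x, what) {
    x <- as.list(x)
    cost <- x$cost %||% x$total_cost
    eff <- x$effect %||% x$total_qaly
    if (is.null(cost) || is.null(eff)) {
      stop("`", what, "` must supply cost and effect", call. = FALSE)
    }
    c(cost = cost[[1]], effect = eff[[1]])
  }
  a <- get_ce(scenario, "scenario")
  b <- get_ce(status_quo, "status_quo")
  if (a[["cost"]] < b[["cost"]]) return("cost_saving")
  ic <- icer(a[["cost"]] - b[["cost"]], a[["effect"]] - b[["effect"]])
  if (!is.na(ic) && ic <= wtp && a[["effect"]] >= b[["effect"]]) {
    return("cost_effective")
  }
  if (is.na(ic) && a[["cost"]] == b[["cost"]]) return("cost_effective")
  "neither"
}

#' Best cost-effective operating point across prevalence and WTP levels
#'
#' Re-runs the cohort model at each prevalence (operating points are
#' prevalence-independent, but costs and QALYs are not), builds the frontier
#' at each willingness-to-pay level, and reports the best cost-effective
#' scenario of every cell.
#'
#' @param points Operating points (tibble with `sensitivity`,
#'   `specificity`, optionally `scenario_id`).
#' @param params A [default_parameters()] bundle.
#' @param prevalences Vector of prevalence levels.
#' @param wtps Vector of willingness-to-pay thresholds (US$/QALY).
#'
#' @return Tibble with one row per (prevalence, wtp) cell: the BCES
#'   `scenario_id`, `sensitivity` and `specificity`.
#' @export
prevalence_wtp_grid <- function(points, params = default_parameters(),
                                prevalences = c(0.04, 0.08, 0.12),
                                wtps = seq(0, 30828, length.out = 11)) {
  if (!length(prevalences) || !length(wtps)) {
    stop("`prevalences` and `wtps` must be non-empty", call. = FALSE)
  }
  purrr::map_dfr(prevalences, function(p) {
    pars <- params
    pars$cohort$prevalence <- p
    scen <- run_scenarios(points, pars)
    purrr::map_dfr(wtps, function(w) {
      fr <- cea_frontier(scen, wtp = w)
      bces <- select_bces(fr)
      i <- match(bces, scen$scenario_id)
      tibble::tibble(prevalence = p, wtp = w, scenario_id = bces,
                     sensitivity = scen$sensitivity[i],
                     specificity = scen$specificity[i])
    })
  })
}
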