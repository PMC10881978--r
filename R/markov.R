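# Deterministic decision-tree + Markov engine, vectorized over scenarios.
#
# Expanded state space (the five clinical states plus screening-eligibility
# bookkeeping):
#   1 nrdr_screen  non-referable DR, still screened annually
#   2 rdr_screen   referable DR, still screened (never referred, or a prior
#                  false negative) -- re-enters screening every year
#   3 rdr_exited   referable DR that refused referral-confirmed treatment;
#                  follows natural history, no longer screened
#   4 trdr         treated referable DR; continues treatment, not screened
#   5 blind        blindness; not screened
#   6 dead         absorbing
#
# Cycle event order (fixed; documented in the methods vignette):
#   screen -> refer -> treat -> progress -> die -> accrue (end of cycle,
#   discount factor (1 + d)^-cycle, no half-cycle correction).
.STATE_NAMES <- c("nrdr_screen", "rdr_screen", "rdr_exited", "trdr",
                  "blind", "dead")

# `overrides` lets callers (PSA, tornado) replace any scalar parameter with a
# per-scenario vector, keyed "section.field".
.run_engine <- function(se, sp, params, overrides = list(),
                        keep_trace = FALSE) {
  stopifnot(inherits(params, "dr_parameters"))
  k <- max(length(se), length(sp),
           if (length(overrides)) max(lengths(overrides)) else 1L)
  se <- rep_len(as.numeric(se), k)
  sp <- rep_len(as.numeric(sp), k)
  if (anyNA(se) || anyNA(sp) || any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  ov <- function(path, default) {
    v <- overrides[[path]] %||% default
    rep_len(as.numeric(v), k)
  }
  scp <- params$screening; nh <- params$natural_history
  ut <- params$utilities; co <- params$costs; cs <- params$cohort

  prev <- ov("cohort.prevalence", cs$prevalence)
  cr <- ov("screening.compliance_referral", scp$compliance_referral)
  ct <- ov("screening.compliance_treatment", scp$compliance_treatment)
  p_nr <- ov("natural_history.p_nrdr_to_rdr", nh$p_nrdr_to_rdr)
  p_rb <- ov("natural_history.p_rdr_to_blind", nh$p_rdr_to_blind)
  p_tb <- ov("natural_history.p_trdr_to_blind", nh$p_trdr_to_blind)
  u_R0 <- ov("utilities.u_R0", ut$u_R0)
  u_R1 <- ov("utilities.u_R1", ut$u_R1)
  w0 <- ut$r0_r1_ratio / (ut$r0_r1_ratio + 1)
  u_n <- w0 * u_R0 + (1 - w0) * u_R1
  u_r <- ov("utilities.u_rdr", ut$u_rdr)
  u_t <- ov("utilities.u_trdr", ut$u_trdr)
  u_b <- ov("utilities.u_blind", ut$u_blind)
  c_scr <- ov("costs.c_screen_per_person", co$c_screen_per_person)
  c_ex <- ov("costs.c_referral_exam", co$c_referral_exam)
  c_t1 <- ov("costs.c_treat_year1", co$c_treat_year1)
  c_tf <- ov("costs.c_treat_followup", co$c_treat_followup)
  c_b1 <- ov("costs.c_blind_year1", co$c_blind_year1)
  c_bf <- ov("costs.c_blind_followup", co$c_blind_followup)
  dc <- co$cost_discount
  dq <- ut$qaly_discount
  hr <- nh$hazard_ratios
  n <- cs$n

  bad_prob <- function(x) any(!is.finite(x) | x < 0 | x > 1)
  if (bad_prob(prev) || bad_prob(cr) || bad_prob(ct) || bad_prob(p_nr) ||
      bad_prob(p_rb) || bad_prob(p_tb)) {
    stop("a probability parameter lies outside [0, 1]", call. = FALSE)
  }
  if (any(c(c_scr, c_ex, c_t1, c_tf, c_b1, c_bf) < 0)) {
    stop("a cost parameter is negative", call. = FALSE)
  }

  x1 <- n * (1 - prev); x2 <- n * prev
  x3 <- x4 <- x5 <- x6 <- rep(0, k)
  cost <- qaly <- rep(0, k)
  cost_screening <- cost_exam_fp <- cost_exam_tp <- rep(0, k)
  cost_treatment <- cost_blindness <- rep(0, k)
  trace <- if (keep_trace) {
    array(NA_real_, dim = c(cs$horizon + 1L, 6L, k))
  } else NULL
  if (keep_trace) trace[1, , ] <- rbind(x1, x2, x3, x4, x5, x6)
  trace_cost <- trace_qaly <- if (keep_trace) {
    matrix(0, cs$horizon + 1L, k)
  } else NULL

  ages <- cs$start_age + seq_len(cs$horizon) - 1L
  mi <- match(ages, nh$mortality_table$age)
  if (anyNA(mi)) {
    stop("mortality table does not cover ages ",
         paste(ages[is.na(mi)], collapse = ", "), call. = FALSE)
  }
  p_death <- nh$mortality_table$p_death[mi]

  for (cyc in seq_len(cs$horizon)) {
    # 1. screening of eligible states
    screened <- x1 + x2
    cyc_screen <- c_scr * screened
    # 2. referral of positives (true and false) at referral compliance
    ref_tp <- cr * se * x2
    ref_fp <- cr * (1 - sp) * x1
    cyc_ex_tp <- c_ex * ref_tp
    cyc_ex_fp <- c_ex * ref_fp
    # 3. confirmed positives accept treatment or exit screening
    new_trdr <- ct * ref_tp
    new_rdrx <- (1 - ct) * ref_tp
    cyc_treat <- c_t1 * new_trdr + c_tf * x4 # follow-up for pre-existing trdr
    r_scr <- x2 - new_trdr - new_rdrx
    r_ext <- x3 + new_rdrx
    t_all <- x4 + new_trdr
    # 4. natural-history transitions (one transition per cycle)
    new_rdr <- p_nr * x1
    new_blind <- p_rb * (r_scr + r_ext) + p_tb * t_all
    cyc_blind <- c_b1 * new_blind + c_bf * x5
    y1 <- x1 - new_rdr
    y2 <- r_scr * (1 - p_rb) + new_rdr
    y3 <- r_ext * (1 - p_rb)
    y4 <- t_all * (1 - p_tb)
    y5 <- x5 + new_blind
    # 5. state-and-age-specific death
    q <- p_death[cyc]
    qn <- min(1, q * hr[["nrdr"]]); qr <- min(1, q * hr[["rdr"]])
    qt <- min(1, q * hr[["trdr"]]); qb <- min(1, q * hr[["blind"]])
    died <- qn * y1 + qr * (y2 + y3) + qt * y4 + qb * y5
    x1 <- y1 * (1 - qn); x2 <- y2 * (1 - qr); x3 <- y3 * (1 - qr)
    x4 <- y4 * (1 - qt); x5 <- y5 * (1 - qb); x6 <- x6 + died
    # 6. end-of-cycle discounted accrual
    df_c <- (1 + dc)^(-cyc)
    df_q <- (1 + dq)^(-cyc)
    cyc_cost <- cyc_screen + cyc_ex_tp + cyc_ex_fp + cyc_treat + cyc_blind
    cyc_qaly <- u_n * x1 + u_r * (x2 + x3) + u_t * x4 + u_b * x5
    cost <- cost + df_c * cyc_cost
    qaly <- qaly + df_q * cyc_qaly
    cost_screening <- cost_screening + df_c * cyc_screen
    cost_exam_fp <- cost_exam_fp + df_c * cyc_ex_fp
    cost_exam_tp <- cost_exam_tp + df_c * cyc_ex_tp
    cost_treatment <- cost_treatment + df_c * cyc_treat
    cost_blindness <- cost_blindness + df_c * cyc_blind

    tot <- x1 + x2 + x3 + x4 + x5 + x6
    if (any(!is.finite(tot)) || any(abs(tot - n) > 1e-6 * n)) {
      stop("internal consistency error: cohort mass not conserved at cycle ",
           cyc, call. = FALSE)
    }
    if (keep_trace) {
      trace[cyc + 1L, , ] <- rbind(x1, x2, x3, x4, x5, x6)
      trace_cost[cyc + 1L, ] <- df_c * cyc_cost
      trace_qaly[cyc + 1L, ] <- df_q * cyc_qaly
    }
  }
  if (any(!is.finite(cost)) || any(!is.finite(qaly))) {
    stop("internal consistency error: non-finite accruals", call. = FALSE)
  }
  res <- tibble::tibble(
    sensitivity = se, specificity = sp,
    cost_per_person = cost / n, qaly_per_person = qaly / n,
    total_cost = cost, total_qaly = qaly,
    cost_screening = cost_screening, cost_exam_fp = cost_exam_fp,
    cost_exam_tp = cost_exam_tp, cost_treatment = cost_treatment,
    cost_blindness = cost_blindness
  )
  list(result = res, trace = trace, trace_cost = trace_cost,
       trace_qaly = trace_qaly)
}

#' Run the screening decision-tree + Markov cohort model
#'
#' Simulates a closed cohort of diabetic participants through annual
#' AI-based DR screening over the model horizon. Each cycle, participants
#' still in the screening pool are screened (screening cost per person);
#' positives attend a confirmatory examination with probability
#' `compliance_referral` (exam cost); confirmed referable-DR patients accept
#' treatment with probability `compliance_treatment` and move to the treated
#' state (year-1 treatment cost, follow-up cost in later years, no further
#' screening), while refusers exit screening and follow natural history.
#' Untreated referable DR progresses to blindness faster than treated
#' disease; non-referable DR becomes referable at the annual progression
#' probability; everyone faces state-and-age-specific mortality. Costs and
#' QALYs accrue at end of cycle and are discounted at their own annual
#' rates.
#'
#' @param sensitivity,specificity Participant-level operating point of the
#'   screening classifier (the sweep's confusion rates already account for
#'   ungradable-image referral).
#' @param params A [default_parameters()] bundle.
#' @param keep_trace Keep the full state-occupancy trace (default `TRUE`).
#'
#' @return An object of class `cohort_run`: a list with
#'   * `result`: one-row tibble with `cost_per_person`, `qaly_per_person`,
#'     `total_cost`, `total_qaly` and discounted cost components;
#'   * `trace`: tibble of expected state occupancy by cycle (cycle 0 is the
#'     initial distribution) with per-cycle discounted cost and QALY
#'     accruals.
#' @examples
#' run <- run_cohort(0.933, 0.877, default_parameters())
#' run$result[, c("cost_per_person", "qaly_per_person")]
#' @export
run_cohort <- function(sensitivity, specificity,
                       params = default_parameters(), keep_trace = TRUE) {
  check_scalar_prob(sensitivity, "sensitivity")
  check_scalar_prob(specificity, "specificity")
  eng <- .run_engine(sensitivity, specificity, params,
                     keep_trace = keep_trace)
  trace <- NULL
  if (keep_trace) {
    occ <- eng$trace[, , 1]
    colnames(occ) <- .STATE_NAMES
    trace <- dplyr::bind_cols(
      tibble::tibble(cycle = 0:params$cohort$horizon),
      tibble::as_tibble(occ),
      tibble::tibble(discounted_cost = eng$trace_cost[, 1],
                     discounted_qaly = eng$trace_qaly[, 1])
    )
  }
  structure(list(result = eng$result, trace = trace, params = params),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat("<cohort_run>  horizon:", x$params$cohort$horizon, "cycles,  n:",
      x$params$cohort$n, "\n")
  print(x$result[, c("sensitivity", "specificity", "cost_per_person",
                     "qaly_per_person")], ...)
  invisible(x)
}

#' Run the cohort model for a set of operating points
#'
#' Vectorized over scenarios: every row of `points` is run through the same
#' parameter bundle, producing discounted per-person and population-total
#' cost and QALYs.
#'
#' @param points Tibble with `sensitivity` and `specificity` columns (and
#'   optionally `scenario_id`), e.g. the output of
#'   [sweep_operating_points()].
#' @param params A [default_parameters()] bundle.
#'
#' @return Tibble with one row per scenario: `scenario_id`, the operating
#'   point, `cost_per_person`, `qaly_per_person`, `total_cost`, `total_qaly`
#'   and discounted cost components.
#' @export
run_scenarios <- function(points, params = default_parameters()) {
  if (!all(c("sensitivity", "specificity") %in% names(points))) {
    stop("`points` must have sensitivity and specificity columns",
         call. = FALSE)
  }
  if (nrow(points) < 1L) stop("`points` is empty", call. = FALSE)
  eng <- .run_engine(points$sensitivity, points$specificity, params)
  dplyr::bind_cols(
    tibble::tibble(scenario_id = points[["scenario_id"]] %||%
                     seq_len(nrow(points))),
    eng$result
  )
}
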