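#' Individual-level micro-simulation oracle for the cohort model
#'
#' Stochastic re-implementation of the cohort model at the level of single
#' participants: every branch the deterministic engine takes in expectation
#' (screening classification, referral and treatment compliance, disease
#' progression, death) is sampled as a Bernoulli draw per individual, with
#' the identical event order and identical cost/QALY accrual rules. Because
#' the two implementations share nothing but the parameter bundle, agreement
#' of the cohort means with the micro-simulation means (within Monte-Carlo
#' error) is a strong correctness check on both.
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#'
#' @return One-row tibble with mean per-person `cost_per_person` /
#'   `qaly_per_person`, their Monte-Carlo standard errors (`se_cost`,
#'   `se_qaly`) and `n_individuals`.
#' @examples
#' microsim_oracle(0.933, 0.877, default_parameters(), 2000, seed = 1)
#' @export
microsim_oracle <- function(sensitivity, specificity,
                            params = default_parameters(),
                            n_individuals = 20000, seed = 1L) {
  check_scalar_prob(sensitivity, "sensitivity")
  check_scalar_prob(specificity, "specificity")
  check_scalar_count(n_individuals, "n_individuals")
  stopifnot(inherits(params, "dr_parameters"))
  set.seed(seed)

  scp <- params$screening; nh <- params$natural_history
  ut <- params$utilities; co <- params$costs; cs <- params$cohort
  n <- n_individuals
  u_n <- ut$u_nonreferable
  hr <- nh$hazard_ratios
  dc <- co$cost_discount; dq <- ut$qaly_discount

  # states: 1 nrdr_screen, 2 rdr_screen, 3 rdr_exited, 4 trdr, 5 blind, 6 dead
  st <- ifelse(stats::runif(n) < cs$prevalence, 2L, 1L)
  cost <- qaly <- numeric(n)

  ages <- cs$start_age + seq_len(cs$horizon) - 1L
  mi <- match(ages, nh$mortality_table$age)
  if (anyNA(mi)) {
    stop("mortality table does not cover ages ",
         paste(ages[is.na(mi)], collapse = ", "), call. = FALSE)
  }
  p_death <- nh$mortality_table$p_death[mi]

  for (cyc in seq_len(cs$horizon)) {
    df_c <- (1 + dc)^(-cyc)
    df_q <- (1 + dq)^(-cyc)
    # 1. screening
    elig <- st == 1L | st == 2L
    cost[elig] <- cost[elig] + df_c * co$c_screen_per_person
    # 2. classification and referral
    pos <- (st == 2L & stats::runif(n) < sensitivity) |
      (st == 1L & stats::runif(n) < 1 - specificity)
    referred <- pos & stats::runif(n) < scp$compliance_referral
    cost[referred] <- cost[referred] + df_c * co$c_referral_exam
    # 3. treatment decision for confirmed referable DR
    was_trdr <- st == 4L
    accept <- referred & st == 2L & stats::runif(n) < scp$compliance_treatment
    refuse <- referred & st == 2L & !accept
    st[accept] <- 4L
    st[refuse] <- 3L
    cost[accept] <- cost[accept] + df_c * co$c_treat_year1
    cost[was_trdr] <- cost[was_trdr] + df_c * co$c_treat_followup
    # 4. progression (one transition per cycle, from the post-screening state)
    st0 <- st
    u_prog <- stats::runif(n)
    to_rdr <- st0 == 1L & u_prog < nh$p_nrdr_to_rdr
    to_blind <- ((st0 == 2L | st0 == 3L) & u_prog < nh$p_rdr_to_blind) |
      (st0 == 4L & u_prog < nh$p_trdr_to_blind)
    was_blind <- st0 == 5L
    st[to_rdr] <- 2L
    st[to_blind] <- 5L
    cost[to_blind] <- cost[to_blind] + df_c * co$c_blind_year1
    cost[was_blind] <- cost[was_blind] + df_c * co$c_blind_followup
    # 5. death
    q <- p_death[cyc]
    qs <- c(min(1, q * hr[["nrdr"]]), min(1, q * hr[["rdr"]]),
            min(1, q * hr[["rdr"]]), min(1, q * hr[["trdr"]]),
            min(1, q * hr[["blind"]]), 0)
    dies <- st != 6L & stats::runif(n) < qs[st]
    st[dies] <- 6L
    # 6. end-of-cycle utility accrual for survivors
    us <- c(u_n, ut$u_rdr, ut$u_rdr, ut$u_trdr, ut$u_blind, 0)
    qaly <- qaly + df_q * us[st]
  }
  tibble::tibble(
    cost_per_person = mean(cost),
    qaly_per_person = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n),
    se_qaly = stats::sd(qaly) / sqrt(n),
    n_individuals = n
  )
}
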