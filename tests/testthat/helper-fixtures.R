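# Shared fixtures, built in code at test time.

# A ten-participant cohort with hand-constructed probability vectors:
# participants N1..N8 are non-referable, P1..P2 referable. P2 is built as a
# false negative at zero thresholds (all its images look non-referable).
tiny_cohort <- function() {
  mk <- function(id, referable, rows) {
    probs <- do.call(rbind, rows)
    rec <- tibble::tibble(
      participant_id = id,
      image_index = seq_len(nrow(probs)),
      gradable = TRUE,
      p_R0 = probs[, 1], p_R1 = probs[, 2], p_R2 = probs[, 3],
      p_R3s = probs[, 4], p_R3a = probs[, 5]
    )
    tr <- tibble::tibble(participant_id = id, referable = referable,
                         subgroup = "none", age_band = "none")
    list(rec = rec, tr = tr)
  }
  neg_row <- c(0.70, 0.20, 0.06, 0.02, 0.02)
  pos_row <- c(0.05, 0.10, 0.65, 0.10, 0.10)
  parts <- c(
    lapply(sprintf("N%d", 1:8), function(id) {
      mk(id, FALSE, rep(list(neg_row), 2))
    }),
    list(mk("P1", TRUE, list(neg_row, pos_row))),
    # false negative by construction: referable but all images benign-looking
    list(mk("P2", TRUE, rep(list(neg_row), 2)))
  )
  list(
    records = dplyr::bind_rows(lapply(parts, `[[`, "rec")),
    truth = dplyr::bind_rows(lapply(parts, `[[`, "tr"))
  )
}

# Degenerate parameter bundle: no disease flow, no death, no discounting,
# utility one everywhere -- QALYs per person must equal the horizon.
degenerate_parameters <- function(horizon = 30, qaly_discount = 0,
                                  utility = 1) {
  default_parameters(
    screening = screening_parameters(),
    nat_history = natural_history(
      p_nrdr_to_rdr = 0, p_rdr_to_blind = 0, p_trdr_to_blind = 0,
      mortality_table = tibble::tibble(age = 0:200, p_death = 0)
    ),
    utilities = utility_set(
      u_R0 = utility, u_R1 = utility, u_rdr = utility, u_trdr = utility,
      u_blind = utility, qaly_discount = qaly_discount
    ),
    costs = cost_set(cost_discount = 0),
    cohort = cohort_spec(n = 1000, horizon = horizon, prevalence = 0)
  )
}

# Small parameter bundle for fast model runs in tests.
small_parameters <- function(n = 10000, horizon = 30) {
  p <- default_parameters()
  p$cohort <- cohort_spec(n = n, horizon = horizon,
                          prevalence = p$cohort$prevalence)
  p
}

# Exhaustive re-derivation of participant-level confusion counts by direct
# rule application (classify_image per image), independent of the fast
# sweep kernel.
brute_confusion <- function(records, truth, thresholds) {
  pos <- vapply(truth$participant_id, function(id) {
    rec <- records[records$participant_id == id, ]
    classify_participant(rec, thresholds)
  }, logical(1))
  tibble::tibble(
    tp = sum(pos & truth$referable),
    fp = sum(pos & !truth$referable),
    tn = sum(!pos & !truth$referable),
    fn = sum(!pos & truth$referable)
  )
}

# Definition-based frontier oracle: a scenario survives the dominance /
# extended-dominance / WTP workflow iff it maximizes net monetary benefit
# at some willingness-to-pay level in [0, wtp]. Candidate levels are all
# pairwise ICERs (the breakpoints of the piecewise-linear max-NMB
# function) plus the interval ends.
frontier_oracle <- function(scenarios, wtp) {
  cost <- scenarios$cost
  eff <- scenarios$effect
  n <- length(cost)
  pair_icers <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      de <- eff[j] - eff[i]
      if (de != 0) pair_icers <- c(pair_icers, (cost[j] - cost[i]) / de)
    }
  }
  lams <- sort(unique(c(0, wtp, pair_icers[pair_icers >= 0 &
                                             pair_icers <= wtp])))
  on_frontier <- rep(FALSE, n)
  for (lam in lams) {
    nb <- eff * lam - cost
    on_frontier[nb >= max(nb) - 1e-9 * max(1, abs(max(nb)))] <- TRUE
  }
  scenarios$scenario_id[on_frontier]
}

# Random scenario cloud for frontier property tests.
random_scenarios <- function(k, seed) {
  set.seed(seed)
  tibble::tibble(
    scenario_id = seq_len(k),
    cost = stats::runif(k, 0, 1000),
    effect = stats::runif(k, 0, 10)
  )
}
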