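test_that("degenerate cohorts hit the closed-form QALY totals", {
  # no disease, no death, utility 1, no discounting: 30 QALYs per person
  p <- degenerate_parameters(horizon = 30)
  run <- run_cohort(0.9, 0.9, p)
  expect_equal(run$result$qaly_per_person, 30)
  # with discounting the geometric sum u * sum (1+d)^-k applies
  d <- 0.035
  pd <- degenerate_parameters(horizon = 30, qaly_discount = d)
  run_d <- run_cohort(0.9, 0.9, pd)
  expect_equal(run_d$result$qaly_per_person, (1 - (1 + d)^-30) / d,
               tolerance = 1e-12)
  expect_equal(run_d$result$qaly_per_person, 18.3920, tolerance = 1e-4)
  u <- 0.8
  pu <- degenerate_parameters(horizon = 30, qaly_discount = d, utility = u)
  expect_equal(run_cohort(0.9, 0.9, pu)$result$qaly_per_person,
               u * (1 - (1 + d)^-30) / d)
})

test_that("the trace conserves cohort mass with an absorbing death state", {
  p <- small_parameters()
  run <- run_cohort(0.933, 0.877, p)
  tr <- run$trace
  states <- c("nrdr_screen", "rdr_screen", "rdr_exited", "trdr", "blind",
              "dead")
  occ <- as.matrix(tr[states])
  expect_true(all(occ >= 0))
  expect_true(all(abs(rowSums(occ) - p$cohort$n) < 1e-6 * p$cohort$n))
  expect_true(all(diff(tr$dead) >= 0))
  # exit states absorb the screening flow
  exits <- tr$rdr_exited + tr$trdr + tr$blind + tr$dead
  expect_true(all(diff(exits) >= -1e-9))
  # initial distribution splits the cohort by prevalence
  expect_equal(tr$rdr_screen[1], p$cohort$n * p$cohort$prevalence)
  expect_equal(tr$nrdr_screen[1], p$cohort$n * (1 - p$cohort$prevalence))
})

test_that("zero-discount QALYs equal utility-weighted occupancy time", {
  p <- small_parameters()
  p$utilities$qaly_discount <- 0
  run <- run_cohort(0.9, 0.85, p)
  tr <- run$trace[-1, ] # accrual is end-of-cycle
  ut <- p$utilities
  manual <- sum(
    ut$u_nonreferable * tr$nrdr_screen +
      ut$u_rdr * (tr$rdr_screen + tr$rdr_exited) +
      ut$u_trdr * tr$trdr +
      ut$u_blind * tr$blind
  )
  expect_equal(run$result$total_qaly, manual, tolerance = 1e-9)
  expect_equal(sum(tr$discounted_qaly), manual, tolerance = 1e-9)
})

test_that("QALYs rise with sensitivity and FP exam costs fall with specificity", {
  p <- small_parameters()
  se_grid <- seq(0.5, 1, 0.1)
  runs <- run_scenarios(
    tibble::tibble(sensitivity = se_grid, specificity = 0.877), p
  )
  expect_true(all(diff(runs$qaly_per_person) > 0))
  sp_grid <- seq(0.5, 1, 0.1)
  runs_sp <- run_scenarios(
    tibble::tibble(sensitivity = 0.933, specificity = sp_grid), p
  )
  expect_true(all(diff(runs_sp$cost_exam_fp) < 0))
})

test_that("the micro-simulation oracle agrees with the deterministic model", {
  p <- small_parameters()
  det <- run_cohort(0.933, 0.877, p, keep_trace = FALSE)$result
  ms <- microsim_oracle(0.933, 0.877, p, n_individuals = 20000, seed = 7)
  expect_lt(abs(ms$cost_per_person - det$cost_per_person), 3 * ms$se_cost)
  expect_lt(abs(ms$qaly_per_person - det$qaly_per_person), 3 * ms$se_qaly)
})

test_that("oracle and cohort model agree across a parameter lattice", {
  base <- small_parameters()
  corners <- list(
    list(se = 0.7, sp = 0.95, cr = 0.3, ct = 0.9, prev = 0.04),
    list(se = 0.99, sp = 0.5, cr = 0.9, ct = 0.3, prev = 0.12),
    list(se = 0.9, sp = 0.9, cr = 1.0, ct = 1.0, prev = 0.0744),
    list(se = 0.6, sp = 0.6, cr = 0.5, ct = 0.7, prev = 0.20),
    list(se = 1.0, sp = 1.0, cr = 0.5, ct = 0.7, prev = 0.0744),
    list(se = 0.0, sp = 1.0, cr = 0.5, ct = 0.7, prev = 0.0744),
    list(se = 0.933, sp = 0.877, cr = 0.0, ct = 0.7, prev = 0.0744),
    list(se = 0.933, sp = 0.877, cr = 0.5, ct = 0.0, prev = 0.0744)
  )
  for (i in seq_along(corners)) {
    cc <- corners[[i]]
    p <- base
    p$screening$compliance_referral <- cc$cr
    p$screening$compliance_treatment <- cc$ct
    p$cohort$prevalence <- cc$prev
    det <- run_cohort(cc$se, cc$sp, p, keep_trace = FALSE)$result
    ms <- microsim_oracle(cc$se, cc$sp, p, n_individuals = 6000,
                          seed = 100 + i)
    expect_lt(abs(ms$cost_per_person - det$cost_per_person),
              3 * ms$se_cost + 1e-9)
    expect_lt(abs(ms$qaly_per_person - det$qaly_per_person),
              3 * ms$se_qaly + 1e-9)
  }
})

test_that("the micro-simulation reproduces geometric survival in a mortality-only model", {
  p <- degenerate_parameters(horizon = 40)
  p$natural_history$mortality_table <- tibble::tibble(age = 0:200,
                                                      p_death = 0.1)
  ms <- microsim_oracle(0.9, 0.9, p, n_individuals = 20000, seed = 3)
  # expected discounted-free life-years: sum over cycles of survival 0.9^k
  expected <- sum(0.9^seq_len(40))
  expect_lt(abs(ms$qaly_per_person - expected), 3 * ms$se_qaly)
})

test_that("scenario totals are per-person values scaled by cohort size", {
  p <- small_parameters(n = 12345)
  res <- run_scenarios(tibble::tibble(sensitivity = c(0.8, 0.95),
                                      specificity = c(0.9, 0.7)), p)
  expect_equal(res$total_cost, res$cost_per_person * 12345)
  expect_equal(res$total_qaly, res$qaly_per_person * 12345)
  # vectorized run matches one-at-a-time runs
  one <- run_cohort(0.95, 0.7, p, keep_trace = FALSE)$result
  expect_equal(res$cost_per_person[2], one$cost_per_person)
  expect_equal(res$qaly_per_person[2], one$qaly_per_person)
})

test_that("model input errors fail loudly", {
  p <- small_parameters()
  expect_error(run_cohort(1.2, 0.9, p), "sensitivity")
  p_bad <- p
  p_bad$cohort$start_age <- 100 # table ends at 110 < 100 + 29
  expect_error(run_cohort(0.9, 0.9, p_bad), "mortality table")
})
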