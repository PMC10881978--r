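test_that("ICER and NMB reproduce published incremental arithmetic", {
  # most cost-effective scenario: +US$14.834M, +839 QALYs at WTP 30,828
  expect_equal(round(icer(14834000, 839)), 17681)
  expect_equal(nmb(839, 14834000, 30828), 11030692)
  # most cost-saving scenario: -US$5.544M, -1490 QALYs
  expect_equal(icer(-5544000, -1490), 3720.8, tolerance = 1e-4)
  expect_equal(nmb(-1490, -5544000, 30828), -40389720)
  expect_equal(icer(0, 5), 0)
  expect_true(is.na(icer(10, 0)))
  expect_equal(nmb(0, 0, 30828), 0)
})

test_that("predictive values follow Bayes' rule at published operating points", {
  m <- diagnostic_metrics(0.933, 0.877, 0.08)
  expect_equal(round(m$ppv, 3), 0.397)
  expect_equal(round(m$npv, 3), 0.993)
  expect_equal(diagnostic_metrics(0.958, 0.824, 0.04)$ppv, 0.185,
               tolerance = 5e-3)
  perfect <- diagnostic_metrics(1, 1, 0.3)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  # chance line: ppv equals prevalence when se = 1 - sp
  chance <- diagnostic_metrics(0.4, 0.6, 0.13)
  expect_equal(chance$ppv, 0.13)
  # degenerate denominator flagged, not divided
  expect_true(is.na(diagnostic_metrics(0, 1, 0.5)$ppv))
  # expected counts scale with n
  cnt <- diagnostic_metrics(0.9, 0.8, 0.1, n = 1000)
  expect_equal(cnt$e_tp, 90)
  expect_equal(cnt$e_fp, 180)
  expect_equal(cnt$e_tp + cnt$e_fp + cnt$e_tn + cnt$e_fn, 1000)
})

test_that("error-count deltas between operating points match the formulas", {
  d <- delta_counts(c(0.933, 0.877), c(0.963, 0.804), 0.08, 251535)
  expect_equal(round(d$decrease_fn), 604)
  d4 <- delta_counts(c(0.933, 0.877), c(0.958, 0.824), 0.04, 251535)
  expect_equal(d4$increase_fp, 251535 * 0.96 * (0.877 - 0.824))
  expect_equal(round(d4$increase_fp), 12798)
  same <- delta_counts(c(0.9, 0.9), c(0.9, 0.9), 0.1, 1000)
  expect_equal(same$increase_fp, 0)
  expect_equal(same$decrease_fn, 0)
})

test_that("the frontier removes dominated and extended-dominated scenarios", {
  s <- tibble::tibble(scenario_id = c("A", "B", "C"),
                      cost = c(0, 100, 110), effect = c(0, 1, 2))
  fr <- cea_frontier(s, wtp = 1000)
  lab <- tidy(fr)
  expect_equal(lab$label[lab$scenario_id == "B"], "extended_dominated")
  expect_equal(lab$icer_vs_prev[lab$scenario_id == "C"], 55)
  expect_setequal(fr$frontier, c("A", "C"))
  # a strictly worse scenario is plainly dominated
  s2 <- tibble::tibble(scenario_id = c("A", "B"), cost = c(0, 10),
                       effect = c(0, -1))
  expect_equal(tidy(cea_frontier(s2, 1000))$label, c("cost_effective",
                                                     "dominated"))
  # single scenario is trivially on the frontier
  fr1 <- cea_frontier(s[1, ], wtp = 10)
  expect_equal(tidy(fr1)$label, "cost_effective")
  expect_error(cea_frontier(s[0, ], 10), "empty")
})

test_that("frontier labels match the definition-based oracle on random clouds", {
  wtps <- c(50, 120, 400)
  for (trial in 1:100) {
    s <- random_scenarios(k = sample(2:10, 1), seed = 2000 + trial)
    w <- wtps[1 + trial %% 3]
    fr <- cea_frontier(s, wtp = w)
    got <- sort(fr$frontier)
    want <- sort(frontier_oracle(s, w))
    expect_equal(got, want,
                 info = sprintf("trial %d (wtp %g)", trial, w))
    # frontier ICERs strictly increase along the frontier (in frontier order)
    lab <- tidy(fr)
    ic <- lab$icer_vs_prev[match(fr$frontier, lab$scenario_id)]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
    # the ICER-stepped frontier's last member is the NMB argmax
    nb <- s$effect * w - s$cost
    expect_equal(fr$bces_id, s$scenario_id[which.max(nb)])
  }
})

test_that("status-quo comparison labels cost-saving and cost-effective scenarios", {
  # per-person costs/effects shaped like a published scenario table
  s <- tibble::tibble(
    scenario_id = 1:3,
    cost = c(6214, 6192, 6273) * 251535,
    effect = c(9.1689, 9.1630, 9.1722) * 251535
  )
  fr <- cea_frontier(s, wtp = 30828, status_quo = 1)
  lab <- tidy(fr)
  expect_equal(lab$label[2], "cost_saving")
  expect_equal(lab$label[1], "status_quo")
  expect_equal(lab$label[3], "cost_effective")
  expect_equal(select_bces(fr), 3)
  expect_equal(classify_vs_status_quo(s[2, ], s[1, ], 30828), "cost_saving")
  expect_equal(classify_vs_status_quo(s[3, ], s[1, ], 30828),
               "cost_effective")
  # an expensive low-gain scenario is neither
  dear <- tibble::tibble(cost = s$cost[1] + 1e9, effect = s$effect[1] + 1)
  expect_equal(classify_vs_status_quo(dear, s[1, ], 30828), "neither")
})

test_that("BCES selection maximizes effect with cost tie-break", {
  s <- tibble::tibble(scenario_id = c("x", "y", "z"),
                      cost = c(5, 6, 1), effect = c(2, 2, 0.5))
  fr <- cea_frontier(s, wtp = 1e6)
  expect_equal(select_bces(fr), "x")
  # nothing eligible -> empty-frontier signal
  fr$bces_id <- NULL
  expect_error(select_bces(fr), "no scenario")
})

test_that("duplicate operating points share their representative's fate", {
  s <- tibble::tibble(scenario_id = 1:4,
                      cost = c(0, 100, 100, 110),
                      effect = c(0, 1, 1, 2))
  fr <- cea_frontier(s, wtp = 1000)
  lab <- tidy(fr)
  expect_equal(lab$label[2], lab$label[3])
})

test_that("the prevalence-by-WTP grid reports a BCES per cell", {
  p <- small_parameters(n = 5000)
  pts <- tibble::tibble(
    scenario_id = 1:4,
    sensitivity = c(0.85, 0.90, 0.95, 0.99),
    specificity = c(0.95, 0.90, 0.82, 0.60)
  )
  grid <- prevalence_wtp_grid(pts, p, prevalences = c(0.04, 0.12),
                              wtps = c(0, 15000, 30828))
  expect_equal(nrow(grid), 6)
  # at WTP 0 the BCES is the cost-minimizing scenario
  for (pv in c(0.04, 0.12)) {
    scen <- run_scenarios(pts, {
      pp <- p
      pp$cohort$prevalence <- pv
      pp
    })
    cheapest <- scen$scenario_id[which.min(scen$total_cost)]
    expect_equal(grid$scenario_id[grid$prevalence == pv & grid$wtp == 0],
                 cheapest)
  }
  # BCES sensitivity is non-decreasing in WTP at fixed prevalence
  for (pv in unique(grid$prevalence)) {
    g <- grid[grid$prevalence == pv, ]
    g <- g[order(g$wtp), ]
    expect_true(all(diff(g$sensitivity) >= 0))
  }
})
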