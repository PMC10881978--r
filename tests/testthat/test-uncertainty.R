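test_that("method-of-moments fits recover beta and gamma parameters", {
  b <- fit_beta_mm(0.5, 0.05)
  expect_equal(unname(b), c(49.5, 49.5))
  # round-trip: the fitted distribution has the requested moments
  m <- 0.3; s <- 0.04
  b2 <- fit_beta_mm(m, s)
  expect_equal(b2[["alpha"]] / sum(b2), m, tolerance = 1e-9)
  v <- prod(b2) / (sum(b2)^2 * (sum(b2) + 1))
  expect_equal(v, s^2, tolerance = 1e-9)
  expect_error(fit_beta_mm(0.5, 0.6), "se")

  g <- fit_gamma_mm(100, 20)
  expect_equal(unname(g), c(25, 4))
  expect_equal(g[["shape"]] * g[["scale"]], 100)
  expect_equal(g[["shape"]] * g[["scale"]]^2, 400)
  expect_error(fit_gamma_mm(-1, 2), "mean")

  # Monte-Carlo round trip
  set.seed(1)
  draws <- rbeta(1e5, b[["alpha"]], b[["beta"]])
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.05 / sqrt(1e5))
  draws_g <- rgamma(1e5, shape = g[["shape"]], scale = g[["scale"]])
  expect_lt(abs(mean(draws_g) - 100), 3 * 20 / sqrt(1e5))
})

test_that("univariate bounds are ±10% (±20% for costs) with clamping", {
  p <- small_parameters(n = 3000)
  pts <- tibble::tibble(scenario_id = 1:3,
                        sensitivity = c(0.933, 0.963, 0.882),
                        specificity = c(0.877, 0.804, 0.903))
  tor <- univariate_sweep(pts, p, status_quo = 1,
                          parameters = c("cohort.prevalence",
                                         "costs.c_treat_year1",
                                         "utilities.u_blind"))
  expect_s3_class(tor, "tornado_analysis")
  prev_row <- tor[tor$parameter == "cohort.prevalence", ]
  expect_equal(prev_row$low, 0.0744 * 0.9)
  expect_equal(prev_row$high, 0.0744 * 1.1)
  cost_row <- tor[tor$parameter == "costs.c_treat_year1", ]
  expect_equal(cost_row$low, cost_row$base * 0.8)
  expect_equal(cost_row$high, cost_row$base * 1.2)
  expect_true(all(tor$low <= tor$base & tor$base <= tor$high))
  expect_error(univariate_sweep(pts, p, parameters = "no.such"), "no.such")
})

test_that("a zero-width perturbation reproduces the base case", {
  p <- small_parameters(n = 3000)
  pts <- tibble::tibble(scenario_id = 1:2,
                        sensitivity = c(0.93, 0.96),
                        specificity = c(0.88, 0.80))
  base <- run_scenarios(pts, p)
  again <- run_scenarios(pts, p)
  expect_identical(base, again)
})

test_that("well-separated scenarios keep a stable ranking under perturbation", {
  p <- small_parameters(n = 3000)
  # one scenario hugely better: no single ±10/20% swing can flip the BCES
  pts <- tibble::tibble(scenario_id = 1:2,
                        sensitivity = c(0.30, 0.99),
                        specificity = c(0.95, 0.90))
  tor <- univariate_sweep(pts, p, status_quo = 1)
  expect_true(all(tor$rank_stable))
})

test_that("PSA defaults and distribution table are coherent", {
  p <- default_parameters()
  d <- default_psa_distributions(p)
  expect_true(all(d$family[grepl("^costs", d$name)] == "gamma"))
  expect_true(all(d$family[grepl("utilities|prevalence|compliance|p_",
                                 d$name)] %in% c("beta", "fixed")))
  expect_equal(d$se[d$name == "cohort.prevalence"], 0.1 * 0.0744)
  expect_equal(d$se[d$name == "costs.c_treat_year1"],
               0.2 * p$costs$c_treat_year1)
  expect_equal(formals(run_psa)$n_sims, 10000)
})

test_that("degenerate PSA concentrates on the deterministic optimum", {
  p <- small_parameters(n = 2000)
  pts <- tibble::tibble(scenario_id = 1:3,
                        sensitivity = c(0.85, 0.933, 0.963),
                        specificity = c(0.92, 0.877, 0.804))
  dists <- default_psa_distributions(p)
  dists$family <- "fixed"
  psa <- run_psa(pts, p, distributions = dists, n_sims = 50, seed = 1,
                 wtps = c(0, 30828))
  det <- run_scenarios(pts, p)
  for (w in c(0, 30828)) {
    best <- det$scenario_id[which.max(det$total_qaly * w - det$total_cost)]
    cc <- psa$ceac[psa$ceac$wtp == w, ]
    expect_equal(cc$probability[cc$scenario_id == best], 1)
  }
  # probabilities sum to one at every WTP level
  sums <- tapply(psa$ceac$probability, psa$ceac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("identical scenarios split optimality roughly evenly", {
  p <- small_parameters(n = 2000)
  pts <- tibble::tibble(scenario_id = 1:2,
                        sensitivity = c(0.9, 0.9),
                        specificity = c(0.85, 0.85))
  psa <- run_psa(pts, p, n_sims = 400, seed = 2, wtps = 30828)
  prob <- psa$ceac$probability[psa$ceac$scenario_id == 1]
  expect_lt(abs(prob - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("CEAC concentrates as dispersions shrink and PSA is reproducible", {
  p <- small_parameters(n = 2000)
  pts <- tibble::tibble(scenario_id = 1:2,
                        sensitivity = c(0.85, 0.963),
                        specificity = c(0.92, 0.804))
  det <- run_scenarios(pts, p)
  best <- det$scenario_id[which.max(det$total_qaly * 30828 - det$total_cost)]
  top_prob <- sapply(c(1, 0.3, 0.05), function(shrink) {
    d <- default_psa_distributions(p, se_fraction_beta = 0.1 * shrink,
                                   se_fraction_gamma = 0.2 * shrink)
    psa <- run_psa(pts, p, distributions = d, n_sims = 150, seed = 4,
                   wtps = 30828)
    psa$ceac$probability[psa$ceac$scenario_id == best]
  })
  expect_true(all(diff(top_prob) >= 0))
  expect_gt(top_prob[3], 0.95)
  # same seed, same curve
  a <- run_psa(pts, p, n_sims = 60, seed = 9, wtps = 30828)
  b <- run_psa(pts, p, n_sims = 60, seed = 9, wtps = 30828)
  expect_identical(a$ceac, b$ceac)
})

test_that("PSA means stay near deterministic values for centred distributions", {
  p <- small_parameters(n = 2000)
  pts <- tibble::tibble(scenario_id = 1, sensitivity = 0.933,
                        specificity = 0.877)
  det <- run_scenarios(pts, p)
  psa <- run_psa(pts, p, n_sims = 500, seed = 5, wtps = 30828)
  s <- psa$summaries
  # distributions are centred on the base case; first-order agreement
  expect_lt(abs(s$mean_cost - det$total_cost), 3 * s$se_cost)
  expect_lt(abs(s$mean_qaly - det$total_qaly), 3 * s$se_qaly)
})
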