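#' Method-of-moments beta parameters
#'
#' Shape parameters of the beta distribution with the given mean and
#' standard error: `alpha = m (m (1 - m) / v - 1)`,
#' `beta = (1 - m) (m (1 - m) / v - 1)`.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean (1 - mean)`.
#' @return Named vector `c(alpha, beta)`.
#' @examples
#' fit_beta_mm(0.5, 0.05) # alpha = beta = 49.5
#' @export
fit_beta_mm <- function(mean, se) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0 || mean >= 1) {
    abort_field("mean", "must lie strictly inside (0, 1)")
  }
  check_scalar_nonneg(se, "se")
  v <- se^2
  if (v <= 0) abort_field("se", "must be positive")
  if (v >= mean * (1 - mean)) {
    abort_field("se", "variance must be below mean * (1 - mean)")
  }
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters
#'
#' Shape/scale of the gamma distribution with the given mean and standard
#' error: `shape = m^2 / v`, `scale = v / m`.
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#' @return Named vector `c(shape, scale)`.
#' @examples
#' fit_gamma_mm(100, 20) # shape 25, scale 4
#' @export
fit_gamma_mm <- function(mean, se) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0) {
    abort_field("mean", "must be a single positive number")
  }
  check_scalar_nonneg(se, "se")
  if (se <= 0) abort_field("se", "must be positive")
  v <- se^2
  c(shape = mean^2 / v, scale = v / mean)
}

# parameter paths perturbed in both sensitivity analyses; `kind` decides the
# distribution family (beta for probabilities/utilities, gamma for costs)
# and the univariate perturbation width (10% vs 20%)
.SA_PARAMETERS <- tibble::tibble(
  name = c("cohort.prevalence",
           "screening.compliance_referral", "screening.compliance_treatment",
           "natural_history.p_nrdr_to_rdr", "natural_history.p_rdr_to_blind",
           "natural_history.p_trdr_to_blind",
           "utilities.u_R0", "utilities.u_R1", "utilities.u_rdr",
           "utilities.u_trdr", "utilities.u_blind",
           "costs.c_screen_per_person", "costs.c_referral_exam",
           "costs.c_treat_year1", "costs.c_treat_followup",
           "costs.c_blind_year1", "costs.c_blind_followup"),
  kind = c(rep("probability", 11), rep("cost", 6))
)

.param_value <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[parts[1]]][[parts[2]]]
}

#' Default parameter distributions for probabilistic sensitivity analysis
#'
#' Probabilities, utilities, prevalence and transition probabilities get
#' beta distributions; costs get gamma distributions. The per-parameter
#' dispersions default to a standard error of 10% of the mean for the beta
#' family and 20% for the gamma family, mirroring the ranges used in the
#' univariate analysis; override by editing the returned tibble.
#'
#' @param params A [default_parameters()] bundle supplying the means.
#' @param se_fraction_beta,se_fraction_gamma Standard error as a fraction of
#'   the mean for the two families.
#' @return Tibble with `name`, `family` (`"beta"`/`"gamma"`/`"fixed"`),
#'   `mean` and `se`.
#' @export
default_psa_distributions <- function(params = default_parameters(),
                                      se_fraction_beta = 0.10,
                                      se_fraction_gamma = 0.20) {
  means <- vapply(.SA_PARAMETERS$name, .param_value, numeric(1),
                  params = params)
  fam <- ifelse(.SA_PARAMETERS$kind == "probability", "beta", "gamma")
  se <- means * ifelse(fam == "beta", se_fraction_beta, se_fraction_gamma)
  # a beta mean of exactly 0 or 1 cannot carry uncertainty; pin it
  fam[fam == "beta" & (means <= 0 | means >= 1)] <- "fixed"
  fam[se <= 0] <- "fixed"
  tibble::tibble(name = .SA_PARAMETERS$name, family = fam,
                 mean = unname(means), se = unname(se))
}

#' Univariate (tornado) sensitivity analysis
#'
#' Perturbs one parameter at a time to fixed bounds (±10% of the base value
#' for probabilities, utilities, prevalence and transition probabilities;
#' ±20% for costs; probabilities clamped to \[0, 1\]), re-runs the scenario
#' set through the cohort model and the frontier, and reports how the best
#' cost-effective scenario and its net monetary benefit respond.
#'
#' @param points Operating points to evaluate (tibble with `sensitivity`,
#'   `specificity`, optionally `scenario_id`).
#' @param params Base [default_parameters()] bundle.
#' @param status_quo Optional `scenario_id` used as NMB baseline; default is
#'   the maximum-Youden point of `points`.
#' @param parameters Optional subset of parameter paths to perturb
#'   (default: all of [default_psa_distributions()]'s paths).
#'
#' @return A `tornado_analysis` tibble: one row per parameter with the
#'   bound values, BCES id, ICER and NMB at each bound, and `rank_stable`
#'   (whether the BCES matches the base case at both bounds).
#' @export
univariate_sweep <- function(points, params = default_parameters(),
                             status_quo = NULL, parameters = NULL) {
  sa <- .SA_PARAMETERS
  if (!is.null(parameters)) {
    bad <- setdiff(parameters, sa$name)
    if (length(bad)) {
      stop("unknown parameter path(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    sa <- sa[sa$name %in% parameters, ]
  }
  ids <- points[["scenario_id"]] %||% seq_len(nrow(points))
  if (is.null(status_quo)) {
    pts <- points
    pts$scenario_id <- ids
    status_quo <- select_status_quo(pts)$scenario_id
  }

  eval_at <- function(overrides) {
    eng <- .run_engine(points$sensitivity, points$specificity, params,
                       overrides = overrides)
    scen <- dplyr::bind_cols(tibble::tibble(scenario_id = ids), eng$result)
    fr <- cea_frontier(scen, wtp = params$wtp, status_quo = status_quo)
    bces <- select_bces(fr)
    i <- match(bces, fr$scenarios$scenario_id)
    list(bces = bces,
         icer = fr$scenarios$icer_vs_status_quo[i],
         nmb = fr$scenarios$nmb[i])
  }

  base_case <- eval_at(list())
  rows <- purrr::pmap_dfr(sa, function(name, kind) {
    value <- .param_value(params, name)
    rel <- if (kind == "cost") 0.20 else 0.10
    lo <- value * (1 - rel)
    hi <- value * (1 + rel)
    if (kind == "probability") {
      lo <- max(0, lo); hi <- min(1, hi)
    }
    at_lo <- eval_at(stats::setNames(list(lo), name))
    at_hi <- eval_at(stats::setNames(list(hi), name))
    stable <- identical(at_lo$bces, base_case$bces) &&
      identical(at_hi$bces, base_case$bces)
    tibble::tibble(
      parameter = name, kind = kind, base = value, low = lo, high = hi,
      bces_low = at_lo$bces, bces_high = at_hi$bces,
      icer_low = at_lo$icer, icer_high = at_hi$icer,
      nmb_low = at_lo$nmb, nmb_high = at_hi$nmb,
      rank_stable = stable
    )
  })
  attr(rows, "base") <- base_case
  attr(rows, "status_quo") <- status_quo
  class(rows) <- c("tornado_analysis", class(rows))
  rows
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' Monte-Carlo propagation of parameter uncertainty: each draw samples
#' every uncertain parameter from its beta or gamma distribution, re-runs
#' the cohort model for every scenario, and records which scenario
#' maximizes net monetary benefit at each willingness-to-pay level (NMB
#' ties broken uniformly at random within the draw). The
#' cost-effectiveness acceptability curve (CEAC) is, per WTP level, the
#' fraction of draws in which each scenario is optimal.
#'
#' @param points Scenarios to compare (tibble with `sensitivity`,
#'   `specificity`, optionally `scenario_id`); typically the frontier
#'   survivors, since the per-draw model cost scales with the number of
#'   scenarios.
#' @param params Base [default_parameters()] bundle.
#' @param distributions Distribution table as from
#'   [default_psa_distributions()].
#' @param n_sims Number of Monte-Carlo draws (default 10,000).
#' @param seed Integer seed.
#' @param wtps Willingness-to-pay grid for the CEAC.
#'
#' @return An object of class `psa_result`: a list with
#'   * `ceac`: tibble `wtp`, `scenario_id`, `probability` (summing to 1 at
#'     each WTP);
#'   * `summaries`: per-scenario mean and SE of cost and QALYs across
#'     draws;
#'   * `n_sims`, `n_resampled` (draws redrawn because a sampled parameter
#'     was invalid).
#' @export
run_psa <- function(points, params = default_parameters(),
                    distributions = default_psa_distributions(params),
                    n_sims = 10000, seed = 1L,
                    wtps = seq(0, 30828, length.out = 11)) {
  check_scalar_count(n_sims, "n_sims")
  if (!all(c("name", "family", "mean", "se") %in% names(distributions))) {
    stop("`distributions` must have name, family, mean, se columns",
         call. = FALSE)
  }
  set.seed(seed)
  k <- nrow(points)
  ids <- points[["scenario_id"]] %||% seq_len(k)

  sample_params <- function(n) {
    draws <- purrr::pmap(distributions, function(name, family, mean, se) {
      switch(family,
             fixed = rep(mean, n),
             beta = {
               sh <- fit_beta_mm(mean, se)
               stats::rbeta(n, sh[["alpha"]], sh[["beta"]])
             },
             gamma = {
               sh <- fit_gamma_mm(mean, se)
               stats::rgamma(n, shape = sh[["shape"]],
                             scale = sh[["scale"]])
             },
             stop("unknown distribution family: ", family, call. = FALSE))
    })
    names(draws) <- distributions$name
    draws
  }

  draws <- sample_params(n_sims)
  # guard: redraw rows where any sampled value is unusable
  valid <- rep(TRUE, n_sims)
  for (j in seq_along(draws)) {
    v <- draws[[j]]
    kind <- .SA_PARAMETERS$kind[match(names(draws)[j], .SA_PARAMETERS$name)]
    bad <- !is.finite(v) | v < 0 |
      (!is.na(kind) & kind == "probability" & v > 1)
    valid <- valid & !bad
  }
  n_resampled <- 0L
  while (any(!valid)) {
    idx <- which(!valid)
    n_resampled <- n_resampled + length(idx)
    redraw <- sample_params(length(idx))
    ok <- rep(TRUE, length(idx))
    for (j in seq_along(draws)) {
      v <- redraw[[j]]
      kind <- .SA_PARAMETERS$kind[match(names(draws)[j],
                                        .SA_PARAMETERS$name)]
      bad <- !is.finite(v) | v < 0 |
        (!is.na(kind) & kind == "probability" & v > 1)
      draws[[j]][idx] <- v
      ok <- ok & !bad
    }
    valid[idx] <- ok
  }
  if (n_resampled > 0.01 * n_sims) {
    warning(sprintf("%d of %d PSA draws required resampling", n_resampled,
                    n_sims))
  }

  # expand to (draw x scenario) and run the engine once
  se_long <- rep(points$sensitivity, times = n_sims)
  sp_long <- rep(points$specificity, times = n_sims)
  overrides <- purrr::map(draws, function(v) rep(v, each = k))
  eng <- .run_engine(se_long, sp_long, params, overrides = overrides)
  cost <- matrix(eng$result$total_cost, nrow = k)
  eff <- matrix(eng$result$total_qaly, nrow = k)

  ceac <- purrr::map_dfr(wtps, function(w) {
    nb <- eff * w - cost
    top <- apply(nb, 2, function(col) {
      mx <- which(col == max(col))
      if (length(mx) > 1L) mx <- sample(mx, 1L)
      mx
    })
    tibble::tibble(wtp = w, scenario_id = ids,
                   probability = tabulate(top, nbins = k) / n_sims)
  })

  summaries <- tibble::tibble(
    scenario_id = ids,
    sensitivity = points$sensitivity,
    specificity = points$specificity,
    mean_cost = rowMeans(cost),
    mean_qaly = rowMeans(eff),
    se_cost = apply(cost, 1, stats::sd) / sqrt(n_sims),
    se_qaly = apply(eff, 1, stats::sd) / sqrt(n_sims)
  )
  structure(
    list(ceac = ceac, summaries = summaries, draws = tibble::as_tibble(draws),
         n_sims = n_sims, n_resampled = n_resampled, wtps = wtps),
    class = "psa_result"
  )
}
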