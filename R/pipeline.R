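#' Read and write cohort tables as CSV
#'
#' Flat UTF-8 CSV with a header and dot decimal separator; the record table
#' has columns `participant_id,image_index,gradable,p_R0,p_R1,p_R2,p_R3s,
#' p_R3a` and the truth table `participant_id,referable,subgroup,age_band`.
#' Writers and readers round-trip losslessly.
#'
#' @param records,truth Cohort tables as produced by [generate_cohort()].
#' @param path File path.
#' @return Readers return the tibble; writers return `path` invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    image_index = readr::col_integer(),
    gradable = readr::col_logical(),
    .default = readr::col_double()
  ))
}

#' @rdname cohort_io
#' @export
write_cohort_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    referable = readr::col_logical(),
    subgroup = readr::col_character(),
    age_band = readr::col_character()
  ))
}

#' Read and write operating-point tables as CSV
#'
#' Columns `scenario_id,step,t_R0,t_R1,t_R2,t_R3s,t_R3a,tp,fp,tn,fn,
#' sensitivity,specificity,youden`.
#'
#' @param points Operating points as produced by
#'   [sweep_operating_points()].
#' @param path File path.
#' @return The reader returns an `operating_points` tibble; the writer
#'   returns `path` invisibly.
#' @name points_io
NULL

#' @rdname points_io
#' @export
write_operating_points <- function(points, path) {
  readr::write_csv(points, path)
  invisible(path)
}

#' @rdname points_io
#' @export
read_operating_points <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    scenario_id = readr::col_integer(),
    step = readr::col_character(),
    tp = readr::col_integer(), fp = readr::col_integer(),
    tn = readr::col_integer(), fn = readr::col_integer(),
    .default = readr::col_double()
  ))
  class(out) <- c("operating_points", class(out))
  out
}

#' Run the full screening cost-effectiveness pipeline
#'
#' Orchestrates the stages end to end -- generate a synthetic cohort, sweep
#' the 1100 threshold vectors, run every operating point through the cohort
#' model, build the cost-effectiveness frontier against the status quo, run
#' the probabilistic sensitivity analysis on the frontier survivors, and
#' optionally evaluate the prevalence-by-WTP grid -- writing every stage's
#' table to `out_dir` plus a JSON summary. Every random stage consumes a
#' named seed derived from `seed`, so a rerun with the same arguments
#' reproduces identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param params A [default_parameters()] bundle (or path handled by
#'   [load_config()]).
#' @param n_participants Synthetic-cohort size.
#' @param seed Master integer seed.
#' @param n_sims PSA draws (0 skips the PSA).
#' @param grid_prevalences,grid_wtps Grids for [prevalence_wtp_grid()];
#'   `NULL` skips the grid stage.
#' @param cohort_config_args Extra arguments passed to [cohort_config()].
#'
#' @return Invisibly, a manifest list: stage output paths, seeds and the
#'   key results (status quo, BCES, frontier object).
#' @export
run_pipeline <- function(out_dir, params = default_parameters(),
                         n_participants = 20000, seed = 1L, n_sims = 500,
                         grid_prevalences = NULL, grid_wtps = NULL,
                         cohort_config_args = list()) {
  if (is.character(params)) params <- load_config(params)
  stopifnot(inherits(params, "dr_parameters"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(cohort = seed, psa = seed + 1L)
  paths <- list()

  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("generate cohort", {
    cfg <- do.call(cohort_config, c(
      list(n_participants = n_participants, seed = seeds$cohort),
      cohort_config_args
    ))
    generate_cohort(cfg)
  })
  paths$records <- file.path(out_dir, "cohort_records.csv")
  paths$truth <- file.path(out_dir, "cohort_truth.csv")
  write_cohort_records(cohort$records, paths$records)
  write_cohort_truth(cohort$truth, paths$truth)

  points <- stage("threshold sweep",
                  sweep_operating_points(cohort$records, cohort$truth))
  paths$points <- file.path(out_dir, "operating_points.csv")
  write_operating_points(points, paths$points)

  scen <- stage("cohort model", run_scenarios(points, params))
  paths$scenarios <- file.path(out_dir, "scenarios.csv")
  readr::write_csv(scen, paths$scenarios)

  sq <- select_status_quo(points)
  fr <- stage("frontier", cea_frontier(scen, wtp = params$wtp,
                                       status_quo = sq$scenario_id))
  paths$frontier <- file.path(out_dir, "frontier.csv")
  readr::write_csv(tidy(fr), paths$frontier)

  psa <- NULL
  if (n_sims > 0) {
    psa <- stage("probabilistic sensitivity analysis", {
      surv <- dplyr::filter(tidy(fr), .data$on_frontier)
      run_psa(dplyr::inner_join(surv["scenario_id"], points,
                                by = "scenario_id"),
              params, n_sims = n_sims, seed = seeds$psa)
    })
    paths$ceac <- file.path(out_dir, "ceac.csv")
    readr::write_csv(psa$ceac, paths$ceac)
  }

  grid <- NULL
  if (!is.null(grid_prevalences) && !is.null(grid_wtps)) {
    grid <- stage("prevalence x WTP grid",
                  prevalence_wtp_grid(points, params,
                                      prevalences = grid_prevalences,
                                      wtps = grid_wtps))
    paths$grid <- file.path(out_dir, "prevalence_wtp_grid.csv")
    readr::write_csv(grid, paths$grid)
  }

  bces_id <- select_bces(fr)
  bces <- points[match(bces_id, points$scenario_id), ]
  summary <- list(
    n_participants = n_participants,
    seeds = seeds,
    auc = empirical_auc(points),
    status_quo = list(scenario_id = sq$scenario_id,
                      sensitivity = sq$sensitivity,
                      specificity = sq$specificity),
    bces = list(scenario_id = bces_id,
                sensitivity = bces$sensitivity,
                specificity = bces$specificity),
    frontier_labels = as.list(table(tidy(fr)$label)),
    wtp = params$wtp,
    outputs = paths
  )
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(paths = paths, seeds = seeds, points = points,
                 scenarios = scen, frontier = fr, psa = psa, grid = grid,
                 status_quo = sq, bces_id = bces_id))
}
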