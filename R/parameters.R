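#' Convert an annual event rate to a transition probability
#'
#' Standard exponential conversion `p(t) = 1 - exp(-r t)` between a constant
#' incidence rate `r` over `t` years and a per-period transition probability.
#'
#' @param r Non-negative annual rate(s).
#' @param t Period length in years (default 1).
#'
#' @return Probability in \[0, 1), monotone increasing in both arguments.
#' @examples
#' rate_to_probability(0.07) # 0.0676
#' @export
rate_to_probability <- function(r, t = 1) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0)) {
    abort_field("r", "must be non-negative rate(s)")
  }
  if (!is.numeric(t) || anyNA(t) || any(t <= 0)) {
    abort_field("t", "must be positive period length(s) in years")
  }
  1 - exp(-r * t)
}

#' Weighted utility of the non-referable DR state
#'
#' The non-referable state pools grades R0 (no DR) and R1 (background DR);
#' its utility is the ratio-weighted mean of the two grade utilities,
#' `(w0 u_R0 + w1 u_R1) / (w0 + w1)` with `w0 : w1` the R0:R1 patient ratio.
#'
#' @param u_R0,u_R1 Grade utilities in \[0, 1\].
#' @param ratio R0:R1 patient ratio, either a single positive number (R0
#'   count per R1 patient, default 5) or a length-2 vector of weights.
#'
#' @return The pooled utility.
#' @examples
#' weighted_nonreferable_utility(0.87, 0.85, 5) # 0.8667
#' @export
weighted_nonreferable_utility <- function(u_R0, u_R1, ratio = 5) {
  check_scalar_prob(u_R0, "u_R0")
  check_scalar_prob(u_R1, "u_R1")
  if (length(ratio) == 2L) {
    w <- as.numeric(ratio)
  } else if (length(ratio) == 1L) {
    w <- c(as.numeric(ratio), 1)
  } else {
    abort_field("ratio", "must be a scalar ratio or two weights")
  }
  if (anyNA(w) || any(w <= 0)) {
    abort_field("ratio", "weights must be positive")
  }
  (w[1] * u_R0 + w[2] * u_R1) / sum(w)
}

#' Synthetic Gompertz-shaped annual mortality table
#'
#' A smooth stand-in for an all-cause age-specific life table: the mortality
#' hazard is `h(age) = h60 * 2^((age - 60) / doubling_years)` and the annual
#' death probability is `1 - exp(-h)`. The default anchors the hazard at
#' 0.008/year at age 60 with an 8-year doubling time, which reproduces the
#' broad shape of adult all-cause mortality; replace it with a real life
#' table via the `mortality_table` field of [natural_history()] when one is
#' available.
#'
#' @param ages Integer ages covered (default 20--110).
#' @param hazard_at_60 Annual mortality hazard at age 60.
#' @param doubling_years Hazard doubling time in years.
#'
#' @return Tibble with `age` and `p_death`.
#' @export
gompertz_mortality_table <- function(ages = 20:110,
                                     hazard_at_60 = 0.008,
                                     doubling_years = 8) {
  check_scalar_nonneg(hazard_at_60, "hazard_at_60")
  check_scalar_nonneg(doubling_years, "doubling_years")
  h <- hazard_at_60 * 2^((ages - 60) / doubling_years)
  tibble::tibble(age = as.integer(ages), p_death = rate_to_probability(h))
}

#' Screening-workflow parameters
#'
#' @param compliance_referral Probability that a screen-positive participant
#'   attends the ophthalmologist referral (default 0.50).
#' @param compliance_treatment Probability that a confirmed referable-DR
#'   patient accepts treatment (default 0.70).
#' @param ungradable_referral Whether ungradable participants are referred
#'   like positives (default `TRUE`; this is what the sweep's participant
#'   positivity rule assumes).
#' @return A `screening_parameters` list.
#' @export
screening_parameters <- function(compliance_referral = 0.50,
                                 compliance_treatment = 0.70,
                                 ungradable_referral = TRUE) {
  check_scalar_prob(compliance_referral, "compliance_referral")
  check_scalar_prob(compliance_treatment, "compliance_treatment")
  if (!is.logical(ungradable_referral) || length(ungradable_referral) != 1L ||
      is.na(ungradable_referral)) {
    abort_field("ungradable_referral", "must be TRUE or FALSE")
  }
  structure(
    list(compliance_referral = compliance_referral,
         compliance_treatment = compliance_treatment,
         ungradable_referral = ungradable_referral),
    class = "screening_parameters"
  )
}

#' Natural-history parameters of DR progression
#'
#' Annual transition probabilities between disease states plus background
#' mortality. The 0.07 default for non-referable to referable progression is
#' a programme-level estimate combining grade-specific progression rates with
#' a 5:1 R0:R1 mix. The blindness progression defaults encode a 4.5-fold
#' annual blindness-risk ratio between untreated and treated referable DR;
#' both are placeholders within published ranges and should be replaced with
#' setting-specific values where available.
#'
#' @param p_nrdr_to_rdr Annual probability non-referable -> referable DR.
#' @param p_rdr_to_blind Annual probability referable DR -> blindness
#'   (untreated).
#' @param p_trdr_to_blind Annual probability treated referable DR ->
#'   blindness.
#' @param mortality_table Tibble with `age` and `p_death`, e.g.
#'   [gompertz_mortality_table()].
#' @param hazard_ratios Named multipliers on age-specific mortality for
#'   states `nrdr`, `rdr`, `trdr`, `blind`; the product is clamped to 1.
#' @return A `natural_history` list.
#' @export
natural_history <- function(p_nrdr_to_rdr = 0.07,
                            p_rdr_to_blind = 0.054,
                            p_trdr_to_blind = 0.012,
                            mortality_table = gompertz_mortality_table(),
                            hazard_ratios = c(nrdr = 1.00, rdr = 1.27,
                                              trdr = 1.15, blind = 2.34)) {
  check_scalar_prob(p_nrdr_to_rdr, "p_nrdr_to_rdr")
  check_scalar_prob(p_rdr_to_blind, "p_rdr_to_blind")
  check_scalar_prob(p_trdr_to_blind, "p_trdr_to_blind")
  if (!is.data.frame(mortality_table) ||
      !all(c("age", "p_death") %in% names(mortality_table))) {
    abort_field("mortality_table", "must have columns age and p_death")
  }
  if (any(mortality_table$p_death < 0 | mortality_table$p_death > 1)) {
    abort_field("mortality_table", "p_death must lie in [0, 1]")
  }
  need <- c("nrdr", "rdr", "trdr", "blind")
  hr <- hazard_ratios
  if (is.list(hr)) hr <- unlist(hr)
  if (!is.numeric(hr) || !all(need %in% names(hr)) || any(hr[need] < 0)) {
    abort_field("hazard_ratios",
                "must be non-negative and name nrdr, rdr, trdr, blind")
  }
  structure(
    list(p_nrdr_to_rdr = p_nrdr_to_rdr,
         p_rdr_to_blind = p_rdr_to_blind,
         p_trdr_to_blind = p_trdr_to_blind,
         mortality_table = tibble::as_tibble(mortality_table),
         hazard_ratios = hr[need]),
    class = "natural_history"
  )
}

#' State-and-age-specific annual mortality probability
#'
#' `min(1, p_death(age) * hazard_ratio(state))`.
#'
#' @param age Integer age; must be covered by the mortality table.
#' @param state One of `"nrdr"`, `"rdr"`, `"trdr"`, `"blind"`.
#' @param nh A [natural_history()] object.
#' @return The annual death probability.
#' @export
mortality_probability <- function(age, state, nh) {
  stopifnot(inherits(nh, "natural_history"))
  state <- match.arg(state, c("nrdr", "rdr", "trdr", "blind"))
  i <- match(age, nh$mortality_table$age)
  if (anyNA(i)) {
    stop(sprintf("age %s not covered by the mortality table",
                 paste(age[is.na(i)], collapse = ", ")), call. = FALSE)
  }
  pmin(1, nh$mortality_table$p_death[i] * nh$hazard_ratios[[state]])
}

#' Health-state utilities
#'
#' Utilities weight each life-year lived in a state; QALYs are discounted
#' annually. The R0/R1 utilities and their 5:1 pooling ratio mirror published
#' candidate values for no-DR and background-DR; the referable, treated and
#' blind utilities are placeholders within published Chinese DR ranges.
#'
#' @param u_R0,u_R1 Utilities of grades R0 and R1.
#' @param r0_r1_ratio R0:R1 patient ratio used to pool them (default 5).
#' @param u_rdr,u_trdr,u_blind Utilities of untreated referable DR, treated
#'   referable DR and blindness.
#' @param qaly_discount Annual QALY discount rate (default 0.035).
#' @return A `utility_set` list; `u_nonreferable` holds the pooled R0/R1
#'   utility.
#' @export
utility_set <- function(u_R0 = 0.87, u_R1 = 0.85, r0_r1_ratio = 5,
                        u_rdr = 0.74, u_trdr = 0.81, u_blind = 0.52,
                        qaly_discount = 0.035) {
  check_scalar_prob(u_rdr, "u_rdr")
  check_scalar_prob(u_trdr, "u_trdr")
  check_scalar_prob(u_blind, "u_blind")
  check_scalar_nonneg(qaly_discount, "qaly_discount")
  u_n <- weighted_nonreferable_utility(u_R0, u_R1, r0_r1_ratio)
  structure(
    list(u_R0 = u_R0, u_R1 = u_R1, r0_r1_ratio = r0_r1_ratio,
         u_nonreferable = u_n, u_rdr = u_rdr, u_trdr = u_trdr,
         u_blind = u_blind, qaly_discount = qaly_discount),
    class = "utility_set"
  )
}

# share of blindness cost that persists past year 1 (indirect costs only)
.BLIND_COST_SPLIT <- c(direct_medical = 0.532, direct_nonmedical = 0.064,
                       indirect = 0.404)

#' Cost parameters (US$)
#'
#' All monetary amounts are US dollars (programme costs recorded in yuan are
#' assumed converted at the 2019 rate of 6.8968 yuan per dollar, stored as
#' metadata). Year-1 blindness cost decomposes as 53.2% direct medical,
#' 6.4% direct non-medical and 40.4% indirect cost; by default only the
#' indirect share recurs in follow-up years.
#'
#' @param c_screen_per_person Per-person cost of one screening visit
#'   (default 10.65; see [build_cost_set()] for its itemization).
#' @param c_referral_exam Cost of a confirmatory ophthalmic examination.
#' @param c_treat_year1 First-year treatment cost (laser photocoagulation
#'   plus anti-VEGF induction) on entry to the treated state.
#' @param c_treat_followup Annual maintenance treatment cost thereafter.
#' @param c_blind_year1 First-year cost on entry to blindness.
#' @param c_blind_followup Annual blindness cost thereafter; defaults to the
#'   indirect share (40.4%) of `c_blind_year1`.
#' @param cost_discount Annual cost discount rate (default 0.03).
#' @param yuan_per_usd Exchange-rate metadata (default 6.8968).
#' @return A `cost_set` list.
#' @export
cost_set <- function(c_screen_per_person = 10.65,
                     c_referral_exam = 60,
                     c_treat_year1 = 1450,
                     c_treat_followup = 290,
                     c_blind_year1 = 4000,
                     c_blind_followup = NULL,
                     cost_discount = 0.03,
                     yuan_per_usd = 6.8968) {
  check_scalar_nonneg(c_screen_per_person, "c_screen_per_person")
  check_scalar_nonneg(c_referral_exam, "c_referral_exam")
  check_scalar_nonneg(c_treat_year1, "c_treat_year1")
  check_scalar_nonneg(c_treat_followup, "c_treat_followup")
  check_scalar_nonneg(c_blind_year1, "c_blind_year1")
  c_blind_followup <- c_blind_followup %||%
    (.BLIND_COST_SPLIT[["indirect"]] * c_blind_year1)
  check_scalar_nonneg(c_blind_followup, "c_blind_followup")
  check_scalar_nonneg(cost_discount, "cost_discount")
  structure(
    list(c_screen_per_person = c_screen_per_person,
         c_referral_exam = c_referral_exam,
         c_treat_year1 = c_treat_year1,
         c_treat_followup = c_treat_followup,
         c_blind_year1 = c_blind_year1,
         c_blind_followup = c_blind_followup,
         blind_cost_split = .BLIND_COST_SPLIT,
         cost_discount = cost_discount,
         yuan_per_usd = yuan_per_usd),
    class = "cost_set"
  )
}

#' Assemble the per-person screening cost from itemized components
#'
#' The screening cost per screened person is
#' `(equipment + personnel + advertisement) / n + AI per participant +
#' participant-side costs` where personnel time follows from programme
#' throughput (one six-camera team screens `participants_per_day` people per
#' working day). When `participant_side_per_person` is `NULL` it is
#' calibrated as the residual that makes the total equal
#' `target_per_person`, absorbing transport, food and income-loss costs that
#' are not itemized separately.
#'
#' @param n_participants Programme size (default 251,535).
#' @param n_cameras Number of fundus cameras (default 6).
#' @param camera_cost Cost per camera over the programme (default US$ 21,749).
#' @param personnel_annual Annual pay of the imaging team (default
#'   US$ 28,999).
#' @param participants_per_day Team throughput (default 288/day).
#' @param working_days_per_year Working days per year (default 250).
#' @param ai_cost_per_participant AI engineering cost per participant
#'   (default US$ 0.214).
#' @param advertisement_total Programme-wide advertisement cost (default
#'   US$ 3,915).
#' @param participant_side_per_person Per-person transport/food/income-loss
#'   cost; `NULL` (default) calibrates it against `target_per_person`.
#' @param target_per_person Total per-person screening cost the components
#'   must reproduce when the participant-side residual is calibrated
#'   (default US$ 10.65); ignored when `participant_side_per_person` is
#'   given.
#' @param ... Further arguments passed to [cost_set()] (examination,
#'   treatment and blindness costs, discount rate).
#'
#' @return A [cost_set()] whose `c_screen_per_person` is the assembled total;
#'   the itemized breakdown is attached as the `"screen_components"`
#'   attribute.
#' @examples
#' cs <- build_cost_set()
#' cs$c_screen_per_person # 10.65
#' attr(cs, "screen_components")
#' @export
build_cost_set <- function(n_participants = 251535,
                           n_cameras = 6,
                           camera_cost = 21749,
                           personnel_annual = 28999,
                           participants_per_day = 288,
                           working_days_per_year = 250,
                           ai_cost_per_participant = 0.214,
                           advertisement_total = 3915,
                           participant_side_per_person = NULL,
                           target_per_person = 10.65,
                           ...) {
  check_scalar_count(n_participants, "n_participants")
  for (f in c("n_cameras", "camera_cost", "personnel_annual",
              "participants_per_day", "working_days_per_year",
              "ai_cost_per_participant", "advertisement_total")) {
    check_scalar_nonneg(get(f), f)
  }
  equipment_pp <- n_cameras * camera_cost / n_participants
  team_years <- if (participants_per_day > 0 && working_days_per_year > 0) {
    n_participants / participants_per_day / working_days_per_year
  } else 0
  personnel_pp <- personnel_annual * team_years / n_participants
  advert_pp <- advertisement_total / n_participants
  fixed_pp <- equipment_pp + personnel_pp + advert_pp + ai_cost_per_participant
  if (is.null(participant_side_per_person)) {
    check_scalar_nonneg(target_per_person, "target_per_person")
    participant_side_per_person <- target_per_person - fixed_pp
    if (participant_side_per_person < 0) {
      abort_field("target_per_person",
                  "is smaller than the itemized components it must absorb")
    }
  } else {
    check_scalar_nonneg(participant_side_per_person,
                        "participant_side_per_person")
  }
  total_pp <- fixed_pp + participant_side_per_person
  out <- cost_set(c_screen_per_person = total_pp, ...)
  attr(out, "screen_components") <- tibble::tibble(
    component = c("equipment", "personnel", "advertisement", "ai",
                  "participant_side"),
    per_person = c(equipment_pp, personnel_pp, advert_pp,
                   ai_cost_per_participant, participant_side_per_person)
  )
  out
}

#' Cohort specification
#'
#' @param n Cohort size (default 251,535, the screening-programme scale the
#'   defaults emulate).
#' @param start_age Mean age at entry in years (default 60).
#' @param horizon Number of one-year Markov cycles (default 30).
#' @param prevalence Baseline prevalence of referable DR (default 0.0744).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 251535, start_age = 60, horizon = 30,
                        prevalence = 0.0744) {
  check_scalar_count(n, "n")
  check_scalar_count(horizon, "horizon")
  check_scalar_nonneg(start_age, "start_age")
  check_scalar_prob(prevalence, "prevalence")
  structure(
    list(n = as.integer(n), start_age = start_age,
         horizon = as.integer(horizon), prevalence = prevalence),
    class = "cohort_spec"
  )
}

# willingness-to-pay presets (US$/QALY): 3x and 1x per-capita GDP, plus
# region-specific levels
.WTP_PRESETS <- c(base = 30828, one_gdp = 10276, rural = 25751, urban = 37259)

#' Willingness-to-pay presets
#'
#' Convenience table of US$/QALY thresholds: `base` is 3x per-capita GDP
#' (the WHO convention), `one_gdp` a stricter 1x GDP level, and `rural` /
#' `urban` region-specific 3x-GDP levels.
#'
#' @return Tibble with `preset` and `wtp`.
#' @export
wtp_presets <- function() {
  tibble::tibble(preset = names(.WTP_PRESETS), wtp = unname(.WTP_PRESETS))
}

#' Full model parameter bundle
#'
#' Assembles screening, natural-history, utility, cost and cohort parameters
#' plus the willingness-to-pay threshold into one bundle. The `rural` and
#' `urban` presets overlay region-specific prevalence, referral compliance
#' and WTP on the base parameters.
#'
#' @param preset `"base"` (default), `"rural"` or `"urban"`.
#' @param screening,nat_history,utilities,costs,cohort Component objects;
#'   defaults are the respective constructors' defaults (with preset
#'   overlays applied).
#' @param wtp Willingness-to-pay threshold in US$/QALY.
#' @return A `dr_parameters` list with elements `screening`,
#'   `natural_history`, `utilities`, `costs`, `cohort`, `wtp`.
#' @examples
#' params <- default_parameters()
#' params$wtp
#' default_parameters("rural")$cohort$prevalence
#' @export
default_parameters <- function(preset = c("base", "rural", "urban"),
                               screening = NULL, nat_history = NULL,
                               utilities = NULL, costs = NULL,
                               cohort = NULL, wtp = NULL) {
  preset <- match.arg(preset)
  overlay <- switch(
    preset,
    base = list(),
    rural = list(prevalence = 0.0540, compliance_referral = 0.33,
                 wtp = .WTP_PRESETS[["rural"]]),
    urban = list(prevalence = 0.0809, compliance_referral = 0.507,
                 wtp = .WTP_PRESETS[["urban"]])
  )
  screening <- screening %||% screening_parameters(
    compliance_referral = overlay$compliance_referral %||% 0.50
  )
  nat_history <- nat_history %||% natural_history()
  utilities <- utilities %||% utility_set()
  costs <- costs %||% build_cost_set()
  cohort <- cohort %||% cohort_spec(
    prevalence = overlay$prevalence %||% 0.0744
  )
  wtp <- wtp %||% overlay$wtp %||% .WTP_PRESETS[["base"]]
  check_scalar_nonneg(wtp, "wtp")
  structure(
    list(screening = screening, natural_history = nat_history,
         utilities = utilities, costs = costs, cohort = cohort, wtp = wtp),
    class = "dr_parameters"
  )
}

# constructor and argument names accepted in each YAML section
.CONFIG_SECTIONS <- list(
  screening = c("compliance_referral", "compliance_treatment",
                "ungradable_referral"),
  natural_history = c("p_nrdr_to_rdr", "p_rdr_to_blind", "p_trdr_to_blind",
                      "mortality_table", "hazard_ratios"),
  utilities = c("u_R0", "u_R1", "r0_r1_ratio", "u_rdr", "u_trdr", "u_blind",
                "qaly_discount"),
  costs = c("c_screen_per_person", "c_referral_exam", "c_treat_year1",
            "c_treat_followup", "c_blind_year1", "c_blind_followup",
            "cost_discount", "yuan_per_usd"),
  cohort = c("n", "start_age", "horizon", "prevalence")
)

#' Load a model configuration from YAML
#'
#' Reads a YAML file with optional sections `screening`, `natural_history`,
#' `utilities`, `costs`, `cohort` and a top-level `wtp`, validates every key
#' against the parameter schema (unknown keys are rejected by name) and
#' returns a full [default_parameters()] bundle with the file's overrides
#' applied. An empty file yields the default bundle.
#'
#' @param path Path to a YAML file.
#' @return A `dr_parameters` bundle.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("configuration must be a YAML mapping", call. = FALSE)
  }
  unknown_top <- setdiff(names(raw), c(names(.CONFIG_SECTIONS), "wtp"))
  if (length(unknown_top)) {
    stop("unknown configuration key(s): ",
         paste(unknown_top, collapse = ", "), call. = FALSE)
  }
  args <- list()
  ctors <- list(screening = screening_parameters,
                natural_history = natural_history,
                utilities = utility_set,
                costs = cost_set,
                cohort = cohort_spec)
  for (sec in names(.CONFIG_SECTIONS)) {
    vals <- raw[[sec]]
    if (is.null(vals)) next
    if (!is.list(vals)) {
      stop("configuration section `", sec, "` must be a mapping",
           call. = FALSE)
    }
    unknown <- setdiff(names(vals), .CONFIG_SECTIONS[[sec]])
    if (length(unknown)) {
      stop("unknown configuration key(s) in `", sec, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (sec == "natural_history" && !is.null(vals$mortality_table)) {
      mt <- vals$mortality_table
      if (all(c("age", "p_death") %in% names(mt))) {
        mt <- tibble::as_tibble(purrr::map(mt, unlist))
      } else {
        mt <- dplyr::bind_rows(purrr::map(mt, tibble::as_tibble))
      }
      vals$mortality_table <- mt
    }
    args[[sec]] <- do.call(ctors[[sec]], vals)
  }
  default_parameters(
    screening = args$screening, nat_history = args$natural_history,
    utilities = args$utilities, costs = args$costs, cohort = args$cohort,
    wtp = raw$wtp
  )
}
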