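#' Configuration for a synthetic screened cohort
#'
#' Bundles the knobs of the synthetic-cohort generator. The generator stands in
#' for a real screening programme: each diabetic participant contributes a
#' fixed number of fundus images, each image carries a five-grade probability
#' vector (R0, R1, R2, R3s, R3a) as an automated grader would emit, and ground
#' truth is a participant-level referable-DR flag (grade R2 or worse on at
#' least one image).
#'
#' @param n_participants Number of participants to simulate.
#' @param prevalence Participant-level prevalence of referable DR. The default
#'   0.0744 matches a large nationwide screening programme in China.
#' @param images_per_participant Images taken per participant (two per eye in
#'   typical protocols, hence the default 4).
#' @param ungradable_rate Per-image probability that an image is ungradable
#'   (poor quality or poor field location). Ungradable images carry no
#'   probability vector and force referral downstream.
#' @param class_separation Non-negative scalar controlling how strongly an
#'   image's probability mass concentrates on the participant's true grade.
#'   0 gives chance-level grading (AUC 0.5); larger values sharpen the grader.
#'   The default is calibrated so the participant-level threshold sweep
#'   ([sweep_operating_points()]) yields an empirical AUC of about 0.93.
#' @param seed Integer seed; identical configurations generate byte-identical
#'   cohorts.
#'
#' @return A `cohort_config` list.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_participants,
                          prevalence = 0.0744,
                          images_per_participant = 4,
                          ungradable_rate = 0,
                          class_separation = 1.97,
                          seed = 1L) {
  check_scalar_count(n_participants, "n_participants")
  check_scalar_prob(prevalence, "prevalence")
  check_scalar_count(images_per_participant, "images_per_participant")
  check_scalar_prob(ungradable_rate, "ungradable_rate", allow_one = FALSE)
  if (!is.numeric(class_separation) || length(class_separation) != 1L ||
      !is.finite(class_separation) || class_separation < 0) {
    abort_field("class_separation", "must be a single non-negative number")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_field("seed", "must be a single integer")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      prevalence = prevalence,
      images_per_participant = as.integer(images_per_participant),
      ungradable_rate = ungradable_rate,
      class_separation = class_separation,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Dirichlet concentration shared by all images; class_separation moves the
# Dirichlet mean from uniform (separation 0) towards the true grade's vertex.
.DIRICHLET_KAPPA <- 8

# grade mix within each truth class: negatives split R0:R1 = 5:1 (the
# programme-level ratio), positives mostly pre-proliferative disease
.NEGATIVE_GRADE_MIX <- c(5, 1) / 6
.POSITIVE_GRADE_MIX <- c(0.60, 0.15, 0.25)

#' Generate a synthetic screened cohort
#'
#' Draws a participant-level truth table and an image-level record table with
#' the statistical structure an AI-graded screening cohort exhibits. Each
#' participant has one latent true grade (its severity); all of the
#' participant's images share it, which induces the within-participant
#' correlation that participant-level positivity rules ("at least one positive
#' image") are sensitive to. Gradable images draw their five-grade probability
#' vector from a Dirichlet distribution whose mean interpolates between the
#' uniform simplex point and the true grade's vertex as `class_separation`
#' grows; ungradable images are flagged independently per image and carry `NA`
#' probabilities.
#'
#' @param config A [cohort_config()].
#'
#' @return A list with two tibbles:
#'   * `records`: `participant_id`, `image_index`, `gradable`,
#'     `p_R0` ... `p_R3a` (rows with `gradable = FALSE` have `NA` probabilities;
#'     gradable rows sum to 1).
#'   * `truth`: `participant_id`, `referable`, `subgroup`, `age_band`.
#' @examples
#' cohort <- generate_cohort(cohort_config(200, seed = 7))
#' summarize_cohort(cohort$records, cohort$truth)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  set.seed(config$seed)
  n <- config$n_participants
  m <- config$images_per_participant
  s <- config$class_separation

  referable <- stats::runif(n) < config$prevalence
  true_grade <- integer(n)
  n_neg <- sum(!referable)
  n_pos <- sum(referable)
  if (n_neg > 0) {
    true_grade[!referable] <- sample(1:2, n_neg, replace = TRUE,
                                     prob = .NEGATIVE_GRADE_MIX)
  }
  if (n_pos > 0) {
    true_grade[referable] <- sample(3:5, n_pos, replace = TRUE,
                                    prob = .POSITIVE_GRADE_MIX)
  }

  n_img <- n * m
  pid_of_image <- rep(seq_len(n), each = m)
  # Dirichlet(kappa * mean) with mean_j = (1 + s * [j == g]) / (5 + s)
  alpha_base <- .DIRICHLET_KAPPA / (5 + s)
  alpha_true <- .DIRICHLET_KAPPA * (1 + s) / (5 + s)
  alpha <- matrix(alpha_base, nrow = n_img, ncol = 5)
  alpha[cbind(seq_len(n_img), true_grade[pid_of_image])] <- alpha_true

  draws <- matrix(stats::rgamma(n_img * 5L, shape = as.vector(alpha)),
                  nrow = n_img, ncol = 5)
  row_tot <- rowSums(draws)
  degenerate <- row_tot <= 0 | !is.finite(row_tot)
  if (any(degenerate)) { # gamma underflow guard: put all mass on the true grade
    draws[degenerate, ] <- 0
    draws[cbind(which(degenerate), true_grade[pid_of_image[degenerate]])] <- 1
    row_tot[degenerate] <- 1
  }
  probs <- draws / row_tot

  gradable <- stats::runif(n_img) >= config$ungradable_rate
  probs[!gradable, ] <- NA_real_

  ids <- sprintf("P%07d", seq_len(n))
  records <- tibble::tibble(
    participant_id = ids[pid_of_image],
    image_index = rep(seq_len(m), times = n),
    gradable = gradable
  )
  records[.PROB_COLS] <- as.data.frame(probs)
  truth <- tibble::tibble(
    participant_id = ids,
    referable = referable,
    subgroup = "none",
    age_band = "none"
  )
  list(records = records, truth = truth)
}

#' Summarize a screened cohort
#'
#' Consistency-checked counts for a cohort's record and truth tables.
#'
#' @param records Image-level record table as produced by [generate_cohort()].
#' @param truth Participant-level truth table.
#'
#' @return One-row tibble with `n_participants`, `n_images`,
#'   `images_per_participant` (mean), `n_referable`, `prevalence` and
#'   `ungradable_fraction`.
#' @export
summarize_cohort <- function(records, truth) {
  .check_cohort_tables(records, truth)
  tibble::tibble(
    n_participants = nrow(truth),
    n_images = nrow(records),
    images_per_participant = nrow(records) / nrow(truth),
    n_referable = sum(truth$referable),
    prevalence = mean(truth$referable),
    ungradable_fraction = mean(!records$gradable)
  )
}

.check_cohort_tables <- function(records, truth) {
  need_rec <- c("participant_id", "image_index", "gradable", .PROB_COLS)
  missing_rec <- setdiff(need_rec, names(records))
  if (length(missing_rec)) {
    stop("`records` is missing columns: ", paste(missing_rec, collapse = ", "),
         call. = FALSE)
  }
  need_tr <- c("participant_id", "referable")
  missing_tr <- setdiff(need_tr, names(truth))
  if (length(missing_tr)) {
    stop("`truth` is missing columns: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(truth$participant_id)) {
    stop("`truth` has duplicated participant_id values", call. = FALSE)
  }
  orphans <- setdiff(unique(records$participant_id), truth$participant_id)
  if (length(orphans)) {
    stop("records reference participants absent from `truth`: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
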