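#' Enumerate the grade-level threshold grid
#'
#' The grader's raw output for an image is a five-grade probability vector.
#' Decision thresholds on the grid 0, 0.1, ..., 0.9 are imposed per grade in
#' two steps: step 1 varies the thresholds of the referable grades (R2, R3s,
#' R3a) with R0/R1 thresholds pinned at 0 (10^3 combinations, aimed at
#' reducing false positives); step 2 varies the R0/R1 thresholds with the
#' referable-grade thresholds pinned at 0 (10^2 combinations, aimed at
#' reducing false negatives). Together they define 1100 operating points.
#'
#' @return A 1100-row tibble with columns `step` (`"step1"`/`"step2"`) and
#'   `t_R0`, `t_R1`, `t_R2`, `t_R3s`, `t_R3a`, in deterministic lexicographic
#'   order (step 1 first).
#' @export
enumerate_threshold_vectors <- function() {
  g <- .THRESHOLD_GRID
  step1 <- tidyr::expand_grid(t_R2 = g, t_R3s = g, t_R3a = g)
  step1 <- dplyr::mutate(step1, step = "step1", t_R0 = 0, t_R1 = 0)
  step2 <- tidyr::expand_grid(t_R0 = g, t_R1 = g)
  step2 <- dplyr::mutate(step2, step = "step2", t_R2 = 0, t_R3s = 0, t_R3a = 0)
  out <- dplyr::bind_rows(step1, step2)
  dplyr::select(out, dplyr::all_of(c("step", .THRESHOLD_COLS)))
}

.threshold_values <- function(thresholds) {
  if (is.data.frame(thresholds)) {
    if (nrow(thresholds) != 1L) {
      stop("`thresholds` must be a single threshold vector", call. = FALSE)
    }
    t <- as.numeric(thresholds[1, .THRESHOLD_COLS])
  } else if (is.numeric(thresholds) && !is.null(names(thresholds)) &&
             all(.THRESHOLD_COLS %in% names(thresholds))) {
    t <- as.numeric(thresholds[.THRESHOLD_COLS])
  } else if (is.numeric(thresholds) && length(thresholds) == 5L) {
    t <- as.numeric(thresholds)
  } else {
    stop("`thresholds` must be a one-row threshold tibble, a named vector ",
         "with t_R0..t_R3a, or an unnamed numeric vector of length 5",
         call. = FALSE)
  }
  if (anyNA(t) || any(t < 0 | t > 1)) {
    stop("thresholds must be probabilities in [0, 1]", call. = FALSE)
  }
  t
}

#' Classify one image under a threshold vector
#'
#' A grade is *activated* when its probability strictly exceeds its threshold
#' (so a zero threshold keeps any grade with positive probability in play);
#' the image's final grade is the activated grade with the highest
#' probability.
#'
#' @param probs Numeric vector of five grade probabilities (R0, R1, R2, R3s,
#'   R3a).
#' @param thresholds A one-row threshold tibble (see
#'   [enumerate_threshold_vectors()]), a named vector with `t_R0` ... `t_R3a`,
#'   or an unnamed numeric vector of length 5.
#'
#' @return The final grade, one of `"R0"`, `"R1"`, `"R2"`, `"R3s"`, `"R3a"`.
#' @examples
#' classify_image(c(0.1, 0.2, 0.6, 0.05, 0.05), rep(0, 5)) # "R2"
#' classify_image(c(0.1, 0.2, 0.6, 0.05, 0.05), c(0, 0, 0.7, 0, 0)) # "R1"
#' @export
classify_image <- function(probs, thresholds) {
  t <- .threshold_values(thresholds)
  if (!is.numeric(probs) || length(probs) != 5L || anyNA(probs) ||
      any(!is.finite(probs)) || any(probs < 0)) {
    stop("`probs` must be five finite non-negative grade probabilities",
         call. = FALSE)
  }
  active <- which(probs > t)
  if (!length(active)) {
    stop("no grade activated; the threshold vector violates the rule that ",
         "zero-threshold grades stay activated", call. = FALSE)
  }
  .GRADES[active[which.max(probs[active])]]
}

#' Classify one participant under a threshold vector
#'
#' A participant screens positive when at least one gradable image receives a
#' referable grade (R2, R3s or R3a) under the threshold rule, or when any of
#' the participant's images is ungradable (ungradable images are reclassified
#' as positive, reflecting real-world referral practice).
#'
#' @param records Image-level records for one participant (rows of the cohort
#'   record table).
#' @param thresholds Threshold vector as in [classify_image()].
#'
#' @return `TRUE` if the participant screens positive.
#' @export
classify_participant <- function(records, thresholds) {
  if (nrow(records) < 1L) {
    stop("`records` must contain at least one image", call. = FALSE)
  }
  if (length(unique(records$participant_id)) > 1L) {
    stop("`records` must belong to a single participant", call. = FALSE)
  }
  if (any(!records$gradable)) {
    return(TRUE)
  }
  grades <- vapply(
    seq_len(nrow(records)),
    function(i) classify_image(as.numeric(records[i, .PROB_COLS]), thresholds),
    character(1)
  )
  any(grades %in% .REFERABLE_GRADES)
}

# Pre-compute the structures the fast confusion kernel needs.
.sweep_prep <- function(records, truth) {
  .check_cohort_tables(records, truth)
  if (nrow(truth) < 1L || nrow(records) < 1L) {
    stop("cohort is empty", call. = FALSE)
  }
  pidx <- match(records$participant_id, truth$participant_id)
  gradable <- as.logical(records$gradable)
  probs <- as.matrix(records[.PROB_COLS])[gradable, , drop = FALSE]
  if (nrow(probs) && anyNA(probs)) {
    stop("gradable records carry missing probabilities", call. = FALSE)
  }
  list(
    n_part = nrow(truth),
    referable = as.logical(truth$referable),
    probs = probs,
    pg_idx = pidx[gradable],
    has_ungradable = tabulate(pidx[!gradable], nbins = nrow(truth)) > 0,
    n_pos = sum(truth$referable),
    n_neg = sum(!truth$referable)
  )
}

# Participant-level confusion counts for one threshold vector. An image is
# positive when the best activated referable-grade probability strictly
# exceeds the best activated non-referable one (argmax ties fall to the
# lower grade index, i.e. the non-referable side).
.confusion_one <- function(prep, t) {
  p <- prep$probs
  if (nrow(p)) {
    s2 <- ifelse(p[, 3] > t[3], p[, 3], -1)
    s3 <- ifelse(p[, 4] > t[4], p[, 4], -1)
    s4 <- ifelse(p[, 5] > t[5], p[, 5], -1)
    n0 <- ifelse(p[, 1] > t[1], p[, 1], -1)
    n1 <- ifelse(p[, 2] > t[2], p[, 2], -1)
    img_pos <- pmax(s2, s3, s4) > pmax(n0, n1)
    pos_imgs <- tabulate(prep$pg_idx[img_pos], nbins = prep$n_part)
    part_pos <- prep$has_ungradable | pos_imgs > 0
  } else {
    part_pos <- prep$has_ungradable
  }
  tp <- sum(part_pos & prep$referable)
  fp <- sum(part_pos & !prep$referable)
  c(tp = tp, fp = fp, tn = prep$n_neg - fp, fn = prep$n_pos - tp)
}

.op_from_confusion <- function(cf) {
  tibble::tibble(
    tp = cf[["tp"]], fp = cf[["fp"]], tn = cf[["tn"]], fn = cf[["fn"]],
    sensitivity = cf[["tp"]] / (cf[["tp"]] + cf[["fn"]]),
    specificity = cf[["tn"]] / (cf[["tn"]] + cf[["fp"]])
  ) |>
    dplyr::mutate(youden = .data$sensitivity + .data$specificity - 1)
}

#' Compute a participant-level operating point
#'
#' Applies the image-level threshold rule and the participant-level positivity
#' rule to the whole cohort, and tallies the confusion counts against the
#' truth table.
#'
#' @inheritParams classify_participant
#' @param records Image-level cohort record table.
#' @param truth Participant-level truth table.
#'
#' @return One-row tibble with the threshold columns, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity` and `youden`.
#' @export
compute_operating_point <- function(records, truth, thresholds) {
  t <- .threshold_values(thresholds)
  prep <- .sweep_prep(records, truth)
  op <- .op_from_confusion(.confusion_one(prep, t))
  th <- tibble::as_tibble(as.list(stats::setNames(t, .THRESHOLD_COLS)))
  dplyr::bind_cols(th, op)
}

#' Sweep every threshold vector over a cohort
#'
#' Evaluates all 1100 threshold vectors from [enumerate_threshold_vectors()]
#' on a cohort, yielding one participant-level operating point per vector.
#'
#' @inheritParams compute_operating_point
#'
#' @return A 1100-row tibble of class `operating_points` with `scenario_id`,
#'   `step`, the five threshold columns, confusion counts, `sensitivity`,
#'   `specificity` and `youden`, in enumeration order.
#' @examples
#' cohort <- generate_cohort(cohort_config(300, seed = 1))
#' pts <- sweep_operating_points(cohort$records, cohort$truth)
#' select_status_quo(pts)
#' empirical_auc(pts)
#' @export
sweep_operating_points <- function(records, truth) {
  prep <- .sweep_prep(records, truth)
  grid <- enumerate_threshold_vectors()
  tmat <- as.matrix(grid[.THRESHOLD_COLS])
  cf <- vapply(seq_len(nrow(tmat)),
               function(i) .confusion_one(prep, tmat[i, ]),
               numeric(4))
  out <- dplyr::bind_cols(
    tibble::tibble(scenario_id = seq_len(nrow(grid))),
    grid,
    tibble::tibble(tp = cf["tp", ], fp = cf["fp", ],
                   tn = cf["tn", ], fn = cf["fn", ])
  )
  out <- dplyr::mutate(
    out,
    sensitivity = .data$tp / (.data$tp + .data$fn),
    specificity = .data$tn / (.data$tn + .data$fp),
    youden = .data$sensitivity + .data$specificity - 1
  )
  class(out) <- c("operating_points", class(out))
  out
}

#' Select the status-quo operating point
#'
#' The status quo is the most accurate operating point: the one maximizing
#' Youden's J (sensitivity + specificity - 1), the standard optimal-cut-off
#' criterion on a receiver-operating curve. Ties go to the higher sensitivity,
#' then to the earlier point in enumeration order. Users wanting a different
#' baseline can pick any row of the sweep explicitly.
#'
#' @param points An `operating_points` tibble (or any tibble with
#'   `sensitivity`, `specificity` and `youden` columns).
#'
#' @return The selected one-row tibble.
#' @export
select_status_quo <- function(points) {
  if (is.null(points) || nrow(points) < 1L) {
    stop("`points` must contain at least one operating point", call. = FALSE)
  }
  if (!"youden" %in% names(points)) {
    points$youden <- points$sensitivity + points$specificity - 1
  }
  ord <- order(-points$youden, -points$sensitivity, seq_len(nrow(points)))
  points[ord[1L], ]
}

#' Empirical area under the ROC curve of an operating-point cloud
#'
#' Computes the trapezoidal area under the upper-left convex hull of the
#' (1 - specificity, sensitivity) pairs, augmented with the trivial corners
#' (0, 0) and (1, 1) -- the standard non-parametric AUC estimate available
#' from a finite set of operating points.
#'
#' @param points Tibble with `sensitivity` and `specificity` columns.
#'
#' @return The AUC, a number in \[0, 1\].
#' @export
empirical_auc <- function(points) {
  fpr <- 1 - points$specificity
  tpr <- points$sensitivity
  if (nrow(unique(cbind(fpr, tpr))) < 2L) {
    stop("need at least two distinct operating points to estimate an AUC",
         call. = FALSE)
  }
  x <- c(0, fpr, 1)
  y <- c(0, tpr, 1)
  ord <- order(x, -y)
  x <- x[ord]; y <- y[ord]
  keep <- !duplicated(x) # per fpr keep only the highest tpr
  x <- x[keep]; y <- y[keep]
  # upper concave envelope via a monotone-chain scan (slopes must decrease)
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2L) {
      k <- length(hx)
      # drop the last hull point when it falls on/below the new chord
      if ((y[i] - hy[k]) * (hx[k] - hx[k - 1]) >=
          (hy[k] - hy[k - 1]) * (x[i] - hx[k])) {
        hx <- hx[-k]; hy <- hy[-k]
      } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  sum(diff(hx) * (utils::head(hy, -1) + utils::tail(hy, -1)) / 2)
}
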