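test_that("the threshold grid is 1000 step-1 plus 100 step-2 vectors", {
  g <- enumerate_threshold_vectors()
  expect_equal(nrow(g), 1100)
  expect_equal(sum(g$step == "step1"), 1000)
  expect_equal(sum(g$step == "step2"), 100)
  # step 1 pins R0/R1 at zero; step 2 pins the referable grades at zero
  expect_true(all(g$t_R0[g$step == "step1"] == 0 &
                    g$t_R1[g$step == "step1"] == 0))
  expect_true(all(g$t_R2[g$step == "step2"] == 0 &
                    g$t_R3s[g$step == "step2"] == 0 &
                    g$t_R3a[g$step == "step2"] == 0))
  # grid origin first, all thresholds on the 10-value grid
  expect_true(all(g[1, -1] == 0))
  expect_true(all(as.matrix(g[-1]) %in% ((0:9) / 10)))
  expect_false(anyDuplicated(g) > 0)
})

test_that("image classification is argmax over activated grades", {
  expect_equal(classify_image(c(0.9, 0.05, 0.03, 0.01, 0.01), rep(0, 5)),
               "R0")
  # deactivating the top grade hands the decision to the activated runner-up
  p <- c(0.1, 0.2, 0.6, 0.05, 0.05)
  expect_equal(classify_image(p, c(0, 0, 0.7, 0, 0)), "R1")
  expect_equal(classify_image(p, c(0, 0, 0.5, 0, 0)), "R2")
  expect_error(classify_image(c(0.1, 0.2), rep(0, 5)), "five")
})

test_that("participant positivity needs one referable image or any ungradable one", {
  neg <- tibble::tibble(
    participant_id = "A", image_index = 1:4, gradable = TRUE,
    p_R0 = 0.8, p_R1 = 0.1, p_R2 = 0.05, p_R3s = 0.03, p_R3a = 0.02
  )
  zeros <- rep(0, 5)
  expect_false(classify_participant(neg, zeros))
  pos <- neg
  pos[4, c("p_R0", "p_R2")] <- list(0.05, 0.8)
  expect_true(classify_participant(pos, zeros))
  ungr <- neg
  ungr$gradable[2] <- FALSE
  expect_true(classify_participant(ungr, zeros))
})

test_that("operating points count participant-level confusion correctly", {
  co <- tiny_cohort()
  op <- compute_operating_point(co$records, co$truth, rep(0, 5))
  # P2 is a false negative by construction
  expect_equal(op$tp, 1)
  expect_equal(op$fn, 1)
  expect_equal(op$sensitivity, 0.5)
  expect_equal(op$tn, 8)
  expect_equal(op$fp, 0)
  expect_equal(op$specificity, 1)
  expect_equal(op$youden, 0.5)
  expect_error(compute_operating_point(co$records[0, ], co$truth[0, ],
                                       rep(0, 5)), "empty")
})

test_that("the fast sweep kernel equals exhaustive rule application", {
  co <- generate_cohort(cohort_config(20, prevalence = 0.3,
                                      class_separation = 1.2,
                                      ungradable_rate = 0.1, seed = 9))
  g <- enumerate_threshold_vectors()
  for (i in c(1, 57, 333, 999, 1001, 1050, 1100)) {
    fast <- compute_operating_point(co$records, co$truth, g[i, ])
    slow <- brute_confusion(co$records, co$truth, g[i, ])
    expect_equal(fast[c("tp", "fp", "tn", "fn")], slow,
                 ignore_attr = TRUE)
  }
})

test_that("sweeps preserve cohort totals and threshold monotonicity", {
  co <- generate_cohort(cohort_config(400, prevalence = 0.25,
                                      class_separation = 1.2, seed = 10))
  pts <- sweep_operating_points(co$records, co$truth)
  expect_equal(nrow(pts), 1100)
  n_pos <- sum(co$truth$referable)
  n_neg <- sum(!co$truth$referable)
  expect_true(all(pts$tp + pts$fn == n_pos))
  expect_true(all(pts$tn + pts$fp == n_neg))
  # first point is the all-zero-threshold operating point
  op0 <- compute_operating_point(co$records, co$truth, rep(0, 5))
  expect_equal(pts$sensitivity[1], op0$sensitivity)
  expect_equal(pts$specificity[1], op0$specificity)
  # raising one referable-grade threshold only shrinks the positive set
  slice <- dplyr::arrange(
    dplyr::filter(pts, step == "step1", t_R3s == 0.3, t_R3a == 0.2),
    t_R2
  )
  expect_equal(nrow(slice), 10)
  expect_true(all(diff(slice$sensitivity) <= 1e-12))
  expect_true(all(diff(slice$specificity) >= -1e-12))
  # dually, raising an R0/R1 threshold only grows the positive set
  slice2 <- dplyr::arrange(
    dplyr::filter(pts, step == "step2", t_R1 == 0.4), t_R0
  )
  expect_true(all(diff(slice2$sensitivity) >= -1e-12))
  expect_true(all(diff(slice2$specificity) <= 1e-12))
})

test_that("a fully ungradable cohort refers everyone at every threshold", {
  co <- generate_cohort(cohort_config(50, prevalence = 0.2,
                                      class_separation = 1.2, seed = 12))
  co$records$gradable <- FALSE
  co$records[paste0("p_", c("R0", "R1", "R2", "R3s", "R3a"))] <- NA_real_
  pts <- sweep_operating_points(co$records, co$truth)
  expect_true(all(pts$sensitivity == 1))
  expect_true(all(pts$specificity == 0))
})

test_that("the status quo is the Youden-optimal point with stated tie-breaks", {
  pts <- tibble::tibble(
    sensitivity = c(0.933, 0.963, 0.882),
    specificity = c(0.877, 0.804, 0.903)
  )
  pts$youden <- pts$sensitivity + pts$specificity - 1
  sq <- select_status_quo(pts)
  expect_equal(sq$sensitivity, 0.933)
  expect_equal(sq$youden, 0.810)
  # single point returns itself
  expect_equal(select_status_quo(pts[2, ])$sensitivity, 0.963)
  # equal J: higher sensitivity wins
  tie <- tibble::tibble(sensitivity = c(0.8, 0.9),
                        specificity = c(0.9, 0.8))
  tie$youden <- tie$sensitivity + tie$specificity - 1
  expect_equal(select_status_quo(tie)$sensitivity, 0.9)
  expect_error(select_status_quo(pts[0, ]), "at least one")
})

test_that("empirical AUC is the convex-hull trapezoid area", {
  perfect <- tibble::tibble(sensitivity = c(1, 0), specificity = c(1, 0))
  expect_equal(empirical_auc(perfect), 1)
  # points on the chance diagonal give 0.5
  chance <- tibble::tibble(sensitivity = c(0.3, 0.7),
                           specificity = c(0.7, 0.3))
  expect_equal(empirical_auc(chance), 0.5)
  # hand-computed hull: (0,0)-(0.1,0.8)-(1,1) ignoring the interior point
  pts <- tibble::tibble(sensitivity = c(0.8, 0.5),
                        specificity = c(0.9, 0.6))
  expect_equal(empirical_auc(pts),
               0.1 * 0.8 / 2 + 0.9 * (0.8 + 1) / 2)
  expect_error(empirical_auc(perfect[1, ]), "distinct")
})
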