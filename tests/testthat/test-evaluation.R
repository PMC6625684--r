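test_that("confusion matrix cells partition the cohort at the threshold", {
  co <- cohort_from_scores(c(5, 4, 2, 0, 3, 1),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cm <- confusion_at_threshold(co, threshold = 3)
  expect_identical(cm[c("tp", "fp", "fn", "tn")],
                   list(tp = 2L, fp = 1L, fn = 1L, tn = 2L))
  expect_identical(cm$tp + cm$fn, 3L)  # operative margin
  expect_identical(cm$fp + cm$tn, 3L)  # nonoperative margin

  # threshold 0: every score is >= 0, so no negatives
  cm0 <- confusion_at_threshold(co, threshold = 0)
  expect_identical(cm0$fn, 0L)
  expect_identical(cm0$tn, 0L)

  # all-operative cohort: no false positives or true negatives
  all_op <- cohort_from_scores(c(5, 1), c(TRUE, TRUE))
  cm_op <- confusion_at_threshold(all_op, threshold = 3)
  expect_identical(cm_op$fp + cm_op$tn, 0L)

  expect_error(confusion_at_threshold(example_cohort(0)), "empty")
})

test_that("records with missing scores or labels are excluded and counted", {
  co <- as.data.frame(cohort_from_scores(c(5, 4, 2, 0),
                                         c(TRUE, TRUE, FALSE, FALSE)))
  co$gcs_total[2] <- NA
  cm <- confusion_at_threshold(siti_cohort(co), threshold = 3)
  expect_identical(cm$n_missing_excluded, 1L)
  expect_identical(cm$tp + cm$fp + cm$fn + cm$tn, 3L)
})

test_that("the four screening metrics obey their ratio identities", {
  cm <- list(tp = 152L, fp = 237L, fn = 12L, tn = 470L)
  m <- diagnostic_metrics(cm)
  expect_equal(m$sensitivity * (cm$tp + cm$fn), 152, tolerance = 1e-12)
  expect_equal(m$specificity * (cm$tn + cm$fp), 470, tolerance = 1e-12)
  expect_equal(m$ppv * (cm$tp + cm$fp), 152, tolerance = 1e-12)
  expect_equal(m$npv * (cm$tn + cm$fn), 470, tolerance = 1e-12)
  expect_length(m$undefined, 0)

  # empty denominators are flagged, not fabricated
  m2 <- diagnostic_metrics(list(tp = 0L, fp = 3L, fn = 0L, tn = 4L))
  expect_true(is.na(m2$sensitivity))
  expect_identical(m2$undefined, "sensitivity")
})

test_that("ROC points match hand enumeration on a 4-record cohort", {
  # operative scores {5, 2}, nonoperative {3, 1}; positive <=> score >= t
  co <- cohort_from_scores(c(5, 2, 3, 1), c(TRUE, TRUE, FALSE, FALSE))
  roc <- roc_curve(co)
  expect_identical(roc$threshold, 12:0)
  # hand-computed: t in 6..12 -> (0,0); t in 4..5 -> (0,1/2); t=3 ->
  # (1/2,1/2); t=2 -> (1/2,1); t=1 -> (1,1); t=0 -> (1,1)
  expected_tpr <- c(rep(0, 7), 0.5, 0.5, 0.5, 1, 1, 1)
  expected_fpr <- c(rep(0, 7), 0, 0, 0.5, 0.5, 1, 1)
  expect_equal(roc$tpr, expected_tpr)
  expect_equal(roc$fpr, expected_fpr)
  # endpoints and monotonicity
  expect_equal(unlist(roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[13, c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("single-class cohorts are a degeneracy error for the ROC", {
  co <- cohort_from_scores(c(5, 1), c(TRUE, TRUE))
  expect_error(roc_curve(co), class = "siti_degenerate_error")
})

test_that("AUC is 1 under perfect separation and 1/2 under no signal", {
  sep <- cohort_from_scores(c(11, 11, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(siti_auc(sep), 1)
  same <- cohort_from_scores(rep(c(0, 4, 7), 2),
                             rep(c(TRUE, FALSE), each = 3))
  expect_equal(siti_auc(same), 0.5)
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(424)
  for (i in 1:250) {
    n <- sample(4:20, 1)
    operative <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    scores <- sample(0:11, n, replace = TRUE)
    co <- cohort_from_scores(scores, operative)
    expect_equal(siti_auc(co), mw_auc_oracle(scores, operative),
                 tolerance = 1e-12, label = paste("cohort", i))
  }
})

test_that("swapping the labels maps AUC to its complement", {
  set.seed(77)
  for (i in 1:20) {
    scores <- sample(0:11, 12, replace = TRUE)
    operative <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 10, TRUE))
    a <- siti_auc(cohort_from_scores(scores, operative))
    b <- siti_auc(cohort_from_scores(scores, !operative))
    expect_equal(a, 1 - b, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_spec(n_total = 400, seed = 5))
  scored <- score_cohort(co)
  ref <- as.numeric(pROC::auc(pROC::roc(scored$operative, scored$total,
                                        quiet = TRUE, direction = "<")))
  expect_equal(siti_auc(co), ref, tolerance = 1e-10)
})

test_that("group comparisons use Welch t for means, Pearson X2 for counts", {
  co <- as.data.frame(example_cohort(n = 40, seed = 3))
  # identical values in both groups: t = 0, p = 1
  co$age_years <- 50
  gc <- compare_groups(siti_cohort(co), "age_years")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p_value, 1)

  # numeric comparison matches stats::t.test (Welch) directly
  co2 <- example_cohort(n = 200, seed = 8)
  gc2 <- compare_groups(co2, "siti_total")
  sc <- score_cohort(co2)
  ref <- t.test(sc$total[sc$operative], sc$total[!sc$operative])
  expect_equal(gc2$statistic, unname(ref$statistic))
  expect_equal(gc2$p_value, ref$p.value)
  expect_equal(unname(gc2$group_means),
               c(mean(sc$total[sc$operative]),
                 mean(sc$total[!sc$operative])))

  # 2x2 with identical proportions: X2 = 0
  co3 <- as.data.frame(cohort_from_scores(rep(c(0, 5), 10),
                                          rep(c(TRUE, FALSE), each = 10)))
  co3$mechanism <- rep(c("fall", "mvc"), 10)
  gc3 <- compare_groups(siti_cohort(co3), "mechanism")
  expect_equal(gc3$statistic, 0)

  # hand-computed Pearson chi-squared, no continuity correction:
  # table (10, 20 / 30, 40) -> n(ad-bc)^2 / (r1 r2 c1 c2) = 0.79365...
  n_cells <- c(10, 20, 30, 40)
  co4 <- as.data.frame(cohort_from_scores(rep(0, 100),
                                          rep(c(TRUE, FALSE), c(30, 70))))
  co4$mechanism <- c(rep(c("fall", "mvc"), c(10, 20)),
                     rep(c("fall", "mvc"), c(30, 40)))
  gc4 <- compare_groups(siti_cohort(co4), "mechanism")
  expect_equal(gc4$statistic,
               100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-12)
})

test_that("logistic fits recover closed-form cases", {
  # intercept-only: intercept = log(k / (n - k))
  co <- cohort_from_scores(rep(0, 10), rep(c(TRUE, FALSE), c(3, 7)))
  fit0 <- fit_logistic(co, components = character(0))
  expect_true(fit0$converged)
  expect_equal(unname(fit0$coefficients[1, 1]), log(3 / 7),
               tolerance = 1e-8)

  # single binary predictor: slope = log odds ratio of the 2x2 table
  # temporal present: 8 operative, 4 nonoperative; absent: 3 vs 9
  scores <- c(rep(3, 12), rep(2, 12))  # 3 = GCS 6 + temporal, 2 = GCS 6
  operative <- c(rep(c(TRUE, FALSE), c(8, 4)), rep(c(TRUE, FALSE), c(3, 9)))
  co2 <- cohort_from_scores(scores, operative)
  fit1 <- fit_logistic(co2, components = "temporal")
  lor <- log((8 / 4) / (3 / 9))
  expect_equal(unname(fit1$coefficients["temporal_points", 1]), lor,
               tolerance = 1e-6)
  expect_true(fit1$auc_of_fit >= 0.5 && fit1$auc_of_fit <= 1)

  # perfectly separating predictor: flagged, no coefficients
  co3 <- cohort_from_scores(c(rep(3, 10), rep(2, 10)),
                            rep(c(TRUE, FALSE), each = 10))
  fit2 <- fit_logistic(co3, components = "temporal")
  expect_false(fit2$converged)
  expect_true(fit2$separation)
  expect_null(fit2$coefficients)

  # constant component: rank-deficient design
  expect_error(fit_logistic(co3, components = c("temporal", "edh")),
               "rank-deficient")
})

test_that("the threshold-3 table reproduction checks its own consistency", {
  cm <- list(tp = 152L, fp = 237L, fn = 12L, tn = 470L)
  rep3 <- reproduce_table3(cm, nonoperative_total = 707,
                           operative_total = 164)
  expect_equal(rep3$metrics_raw$sensitivity, 152 / 164)
  expect_equal(rep3$metrics_raw$specificity, 470 / 707)
  expect_equal(rep3$metrics_rounded$sensitivity, 0.93)
  expect_equal(rep3$metrics_rounded$specificity, 0.66)
  expect_equal(rep3$metrics_rounded$ppv, 0.39)
  # 470/482 = 0.9751 rounds to 0.98 (the published table prints 0.97)
  expect_equal(rep3$metrics_rounded$npv, 0.98)

  # the published fp = 327 violates the nonoperative margin: 327+470 != 707
  expect_error(
    reproduce_table3(list(tp = 152L, fp = 327L, fn = 12L, tn = 470L),
                     nonoperative_total = 707),
    "327 \\+ 470 = 797 but nonoperative total is 707")

  perfect <- reproduce_table3(list(tp = 1L, fp = 0L, fn = 0L, tn = 1L),
                              nonoperative_total = 1)
  expect_true(all(unlist(perfect$metrics_rounded) == 1))
})

test_that("diagnostic reports serialize to stable JSON", {
  co <- example_cohort(n = 60, seed = 21)
  rep <- diagnostic_report(co)
  js <- jsonlite::fromJSON(report_json(rep))
  expect_identical(js$threshold, rep$threshold)
  expect_identical(js$confusion$tp, rep$cm$tp)
  expect_equal(js$auc, rep$auc)
  expect_identical(js$config$schema_version, "1")
  f <- withr::local_tempfile(fileext = ".json")
  report_json(rep, f)
  expect_equal(jsonlite::fromJSON(f)$auc, rep$auc)
})
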