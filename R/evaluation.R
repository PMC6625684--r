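# Diagnostic evaluation of the SITI score against the operative label
# (craniotomy/craniectomy within 24 h): confusion matrix, the four
# screening metrics, ROC over integer score thresholds, trapezoidal AUC,
# two-group comparisons, and logistic models of surgery odds.

SITI_COMPONENTS <- c("gcs", "pupil", "shift", "temporal", "edh")

#' Confusion matrix of the SITI rule at a score threshold
#'
#' Classifies each assessed record as test-positive when its SITI total is
#' at or above `threshold` and crosses that with the operative label.
#' Records with a missing score component or an unresolved label are
#' excluded listwise and counted in `n_missing_excluded`; records flagged
#' for exclusion are removed first via [apply_exclusions()].
#'
#' @param cohort A `"siti_cohort"`.
#' @param threshold Positivity threshold on the total, default 3.
#' @param edh_strict_gt See [siti_edh_points()].
#' @return An object of class `"siti_confusion"`: a list with integer
#'   cells `tp`, `fp`, `fn`, `tn`, plus `threshold` and
#'   `n_missing_excluded`.
#' @export
confusion_at_threshold <- function(cohort, threshold = 3L,
                                   edh_strict_gt = FALSE) {
  scored <- assessed_scores(cohort, threshold, edh_strict_gt)
  d <- scored$data
  cm <- structure(list(
    tp = sum(d$positive & d$operative),
    fp = sum(d$positive & !d$operative),
    fn = sum(!d$positive & d$operative),
    tn = sum(!d$positive & !d$operative),
    threshold = as.integer(threshold),
    n_missing_excluded = scored$n_missing
  ), class = "siti_confusion")
  cm
}

#' @export
print.siti_confusion <- function(x, ...) {
  cat(sprintf("SITI confusion matrix at threshold %d (score >= %d positive)\n",
              x$threshold, x$threshold))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c(sprintf("score >= %d", x$threshold),
                                sprintf("score <  %d", x$threshold)),
                              c("operative", "nonoperative")))
  print(m)
  if (x$n_missing_excluded > 0) {
    cat(sprintf("  (%d record(s) excluded for missing score or label)\n",
                x$n_missing_excluded))
  }
  invisible(x)
}

#' Sensitivity, specificity, PPV and NPV of a confusion matrix
#'
#' Computes the four screening metrics as exact ratios. A metric whose
#' denominator is zero is returned as `NA` and listed in `undefined`.
#'
#' @param cm A `"siti_confusion"` or a list with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @return A list with `sensitivity` (tp/(tp+fn)), `specificity`
#'   (tn/(tn+fp)), `ppv` (tp/(tp+fp)), `npv` (tn/(tn+fn)) and `undefined`
#'   (character vector of metrics with empty denominators).
#' @export
diagnostic_metrics <- function(cm) {
  with(cm, {
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    out <- list(sensitivity = ratio(tp, tp + fn),
                specificity = ratio(tn, tn + fp),
                ppv = ratio(tp, tp + fp),
                npv = ratio(tn, tn + fn))
    out$undefined <- names(out)[vapply(out, is.na, TRUE)]
    out
  })
}

#' ROC curve of the SITI score over integer thresholds
#'
#' Sweeps the positivity threshold over the integer scores 12 down to 0
#' (positive means score at or above the threshold) and records the
#' false-positive and true-positive rate at each. The curve starts at
#' (0, 0) — threshold 12 exceeds the scale maximum of 11 — and ends at
#' (1, 1), both coordinates nondecreasing.
#'
#' @inheritParams confusion_at_threshold
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`, carrying
#'   `n_missing_excluded` as an attribute.
#' @export
roc_curve <- function(cohort, edh_strict_gt = FALSE) {
  scored <- assessed_scores(cohort, threshold = 3L, edh_strict_gt)
  d <- scored$data
  n_pos <- sum(d$operative)
  n_neg <- sum(!d$operative)
  if (n_pos == 0 || n_neg == 0) {
    stop_degenerate(
      "ROC requires at least one operative and one nonoperative record")
  }
  thresholds <- 12:0
  tpr <- vapply(thresholds, function(t) sum(d$total >= t & d$operative), 0) /
    n_pos
  fpr <- vapply(thresholds, function(t) sum(d$total >= t & !d$operative), 0) /
    n_neg
  out <- data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
  attr(out, "n_missing_excluded") <- scored$n_missing
  out
}

#' Trapezoidal area under a ROC curve
#'
#' Integrates the true-positive rate over the false-positive rate with the
#' trapezoid rule. On a threshold-swept integer-score ROC this equals the
#' Mann-Whitney probability that a random operative patient outscores a
#' random nonoperative one, with ties credited 1/2.
#'
#' @param roc A data.frame with `fpr` and `tpr` columns ordered along the
#'   curve (as returned by [roc_curve()]).
#' @return The area, a number in [0, 1].
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(is.data.frame(roc), all(c("fpr", "tpr") %in% names(roc)))
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' AUC of the SITI score on a labeled cohort
#'
#' Convenience wrapper: [roc_curve()] followed by [auc_trapezoid()].
#'
#' @inheritParams roc_curve
#' @return The area under the curve.
#' @export
siti_auc <- function(cohort, edh_strict_gt = FALSE) {
  auc_trapezoid(roc_curve(cohort, edh_strict_gt = edh_strict_gt))
}

#' Compare a variable between operative and nonoperative patients
#'
#' Numeric variables are compared with a t-test on the group means (Welch
#' by default, pooled-variance optional); categorical variables with a
#' Pearson chi-squared test (no continuity correction) on the contingency
#' table of counts.
#'
#' @param cohort A `"siti_cohort"`; records flagged for exclusion are
#'   removed first.
#' @param variable Name of a cohort column, or one of `"siti_total"` (the
#'   computed score) to compare mean scores.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return An object of class `"siti_group_comparison"`: variable name,
#'   test used, per-group means or proportion tables, `statistic` and
#'   `p_value` (both `NA` with `degenerate = TRUE` when a margin of the
#'   table is zero).
#' @export
compare_groups <- function(cohort, variable, var_equal = FALSE) {
  d <- score_cohort(apply_exclusions(cohort)$cohort)
  d$siti_total <- d$total
  if (!variable %in% names(d)) {
    stop("no such variable in cohort: ", variable, call. = FALSE)
  }
  x <- d[[variable]]
  keep <- !is.na(x) & !is.na(d$operative)
  x <- x[keep]
  op <- d$operative[keep]
  if (sum(op) == 0 || sum(!op) == 0) {
    stop_degenerate("both operative and nonoperative groups must be nonempty")
  }
  if (is.numeric(x)) {
    # degenerate zero-variance case (t.test refuses essentially-constant
    # data): equal means give t = 0, p = 1
    if (stats::var(x[op]) == 0 && stats::var(x[!op]) == 0 &&
        mean(x[op]) == mean(x[!op])) {
      ht <- list(statistic = c(t = 0), p.value = 1)
    } else {
      ht <- stats::t.test(x[op], x[!op], var.equal = var_equal)
    }
    out <- list(variable = variable,
                test = if (var_equal) "t (pooled)" else "t (Welch)",
                group_means = c(operative = mean(x[op]),
                                nonoperative = mean(x[!op])),
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                degenerate = FALSE)
  } else {
    tab <- table(group = factor(op, c(TRUE, FALSE),
                                c("operative", "nonoperative")),
                 value = x)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2) {
      out <- list(variable = variable, test = "chi-squared (Pearson)",
                  table = tab, statistic = NA_real_, p_value = NA_real_,
                  degenerate = TRUE)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out <- list(variable = variable, test = "chi-squared (Pearson)",
                  table = tab, statistic = unname(ht$statistic),
                  p_value = ht$p.value, degenerate = FALSE)
    }
  }
  structure(out, class = "siti_group_comparison")
}

#' @export
print.siti_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' [%s]\n", x$variable, x$test))
  if (!is.null(x$group_means)) print(round(x$group_means, 3))
  if (!is.null(x$table)) print(x$table)
  if (isTRUE(x$degenerate)) {
    cat("  degenerate table (zero margin); no p-value\n")
  } else {
    cat(sprintf("  statistic = %.4f, p = %.4g\n", x$statistic, x$p_value))
  }
  invisible(x)
}

#' Logistic model of surgery odds on SITI components
#'
#' Fits, by iteratively reweighted least squares, a logistic regression of
#' the operative label on the points of a chosen subset of the five SITI
#' components (gcs, pupil, shift, temporal, edh). Reports
#' maximum-likelihood coefficients with standard errors and the AUC of the
#' fitted probabilities against the label. Complete separation is flagged
#' and no coefficients are reported for a nonconverged fit.
#'
#' @param cohort A `"siti_cohort"`.
#' @param components Character subset of
#'   `c("gcs", "pupil", "shift", "temporal", "edh")`; default all five.
#'   An empty subset fits the intercept-only model.
#' @param edh_strict_gt See [siti_edh_points()].
#' @return An object of class `"siti_logistic"`: `components`,
#'   `coefficients` (matrix with estimate and std. error), `converged`,
#'   `separation`, `auc_of_fit`, `n`, and the underlying `glm` fit (when
#'   converged).
#' @export
fit_logistic <- function(cohort, components = SITI_COMPONENTS,
                         edh_strict_gt = FALSE) {
  if (length(components) > 0) {
    components <- match.arg(components, SITI_COMPONENTS, several.ok = TRUE)
  }
  scored <- assessed_scores(cohort, threshold = 3L, edh_strict_gt)
  d <- scored$data
  predictors <- if (length(components) > 0) {
    paste0(components, "_points")
  } else {
    character(0)
  }
  X <- d[predictors]
  if (length(predictors) > 0) {
    qrX <- qr(cbind(1, as.matrix(X)))
    if (qrX$rank < ncol(X) + 1) {
      stop("design matrix is rank-deficient on the included records ",
           "(constant or aliased component)", call. = FALSE)
    }
  }
  dat <- cbind(y = as.integer(d$operative), X)
  form <- if (length(predictors) > 0) {
    stats::reformulate(predictors, response = "y")
  } else {
    y ~ 1
  }
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete/quasi-complete separation: the MLE diverges, which shows up
  # as fitted probabilities numerically at 0/1 with exploding
  # coefficients (glm may stop "converged" on the deviance criterion)
  mu <- stats::fitted(fit)
  separation <- (sep_warning || any(mu < 1e-10 | mu > 1 - 1e-10)) &&
    any(abs(stats::coef(fit)) > 15)
  converged <- fit$converged && !separation
  if (!converged) {
    return(structure(list(components = components, coefficients = NULL,
                          converged = FALSE, separation = separation,
                          diagnostic = if (separation)
                            "complete or quasi-complete separation detected"
                          else "IRLS did not converge",
                          auc_of_fit = NA_real_, n = nrow(d), fit = NULL),
                     class = "siti_logistic"))
  }
  sm <- summary(fit)$coefficients[, 1:2, drop = FALSE]
  structure(list(components = components, coefficients = sm,
                 converged = TRUE, separation = FALSE,
                 auc_of_fit = auc_rank(stats::fitted(fit), d$operative),
                 n = nrow(d), fit = fit),
            class = "siti_logistic")
}

#' @export
print.siti_logistic <- function(x, ...) {
  cat(sprintf("Logistic model of surgery odds on: %s (n = %d)\n",
              paste(x$components, collapse = ", "), x$n))
  if (!x$converged) {
    cat("  NOT converged: ", x$diagnostic, "\n", sep = "")
  } else {
    print(round(x$coefficients, 4))
    cat(sprintf("  AUC of fitted probabilities: %.4f\n", x$auc_of_fit))
  }
  invisible(x)
}

#' Recompute the screening metrics from a confusion matrix, with a
#' consistency check
#'
#' Verifies the matrix against a supplied nonoperative group total (and an
#' operative total if given), then reports sensitivity, specificity, PPV
#' and NPV both as raw ratios and rounded to two decimals
#' (half-away-from-zero), the convention used for published tables.
#'
#' @param cm A `"siti_confusion"` or list with `tp`, `fp`, `fn`, `tn`.
#' @param nonoperative_total Expected `fp + tn`.
#' @param operative_total Optional expected `tp + fn`.
#' @return A list with `cm`, `metrics_raw` and `metrics_rounded`.
#' @export
reproduce_table3 <- function(cm, nonoperative_total,
                             operative_total = NULL) {
  if (cm$fp + cm$tn != nonoperative_total) {
    stop(sprintf(
      "inconsistent counts: fp + tn = %d + %d = %d but nonoperative total is %d",
      cm$fp, cm$tn, cm$fp + cm$tn, nonoperative_total), call. = FALSE)
  }
  if (!is.null(operative_total) && cm$tp + cm$fn != operative_total) {
    stop(sprintf(
      "inconsistent counts: tp + fn = %d + %d = %d but operative total is %d",
      cm$tp, cm$fn, cm$tp + cm$fn, operative_total), call. = FALSE)
  }
  raw <- diagnostic_metrics(cm)
  rounded <- lapply(raw[c("sensitivity", "specificity", "ppv", "npv")],
                    round_half_away, digits = 2)
  list(cm = cm, metrics_raw = raw[c("sensitivity", "specificity",
                                    "ppv", "npv")],
       metrics_rounded = rounded)
}

#' Full diagnostic report for a labeled cohort
#'
#' Runs the whole evaluation at one threshold: exclusion flow, confusion
#' matrix, the four screening metrics (raw and rounded to two decimals),
#' the integer-threshold ROC curve and its trapezoidal AUC, and the
#' missing-record accounting.
#'
#' @inheritParams confusion_at_threshold
#' @return An object of class `"siti_report"`.
#' @export
diagnostic_report <- function(cohort, threshold = 3L,
                              edh_strict_gt = FALSE) {
  excl <- apply_exclusions(cohort)
  cm <- confusion_at_threshold(excl$cohort, threshold, edh_strict_gt)
  raw <- diagnostic_metrics(cm)
  roc <- roc_curve(excl$cohort, edh_strict_gt = edh_strict_gt)
  structure(list(
    threshold = as.integer(threshold),
    cm = cm,
    metrics_raw = raw[c("sensitivity", "specificity", "ppv", "npv")],
    metrics_rounded = lapply(raw[c("sensitivity", "specificity",
                                   "ppv", "npv")],
                             round_half_away, digits = 2),
    undefined = raw$undefined,
    roc_points = roc,
    auc = auc_trapezoid(roc),
    exclusion_tally = excl$tally,
    n_input = excl$n_input,
    n_assessed = excl$n_assessed,
    n_missing_excluded = cm$n_missing_excluded,
    config = list(threshold = as.integer(threshold),
                  edh_strict_gt = edh_strict_gt,
                  tie_rule = "half-credit (trapezoid)",
                  rounding = "2 decimals, half away from zero",
                  schema_version = "1")
  ), class = "siti_report")
}

#' @export
print.siti_report <- function(x, ...) {
  cat(sprintf("SITI diagnostic report (threshold %d)\n", x$threshold))
  cat(sprintf("  records: %d in, %d assessed (%d excluded by reason, %d for missing data)\n",
              x$n_input, x$n_assessed, sum(x$exclusion_tally),
              x$n_missing_excluded))
  print(x$cm)
  m <- x$metrics_rounded
  cat(sprintf("  sensitivity %.2f  specificity %.2f  PPV %.2f  NPV %.2f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  cat(sprintf("  AUC (trapezoid over thresholds 12..0) = %.4f\n", x$auc))
  invisible(x)
}

#' Serialize a diagnostic report to JSON
#'
#' @param report A `"siti_report"`.
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    schema_version = report$config$schema_version,
    threshold = report$threshold,
    confusion = report$cm[c("tp", "fp", "fn", "tn")],
    metrics_raw = report$metrics_raw,
    metrics_rounded = report$metrics_rounded,
    roc_points = report$roc_points,
    auc = report$auc,
    exclusion_tally = as.list(report$exclusion_tally),
    n_input = report$n_input,
    n_assessed = report$n_assessed,
    n_missing_excluded = report$n_missing_excluded,
    config = report$config
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# ---- internals --------------------------------------------------------------

# Score the cohort and drop records with missing components or labels,
# counting them. Errors on an empty cohort.
assessed_scores <- function(cohort, threshold, edh_strict_gt) {
  d <- score_cohort(cohort, threshold = threshold,
                    edh_strict_gt = edh_strict_gt)
  if (nrow(d) == 0) stop("cohort is empty", call. = FALSE)
  complete <- !is.na(d$total) & !is.na(d$operative)
  list(data = d[complete, , drop = FALSE],
       n_missing = sum(!complete))
}

# Rank-based (Mann-Whitney) AUC for a continuous marker, ties half-credited.
auc_rank <- function(marker, label) {
  r <- rank(marker)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Statistical degeneracy (e.g. single-class cohort): its own condition
# class so callers (the CLI in particular) can map it to a distinct exit
# code.
stop_degenerate <- function(msg) {
  stop(structure(class = c("siti_degenerate_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
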