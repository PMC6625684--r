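# Independent oracles and cohort builders used across the suite.

# Brute-force Mann-Whitney AUC: P(score_op > score_nonop) + 1/2 P(equal),
# enumerated over all operative x nonoperative pairs. Independent of the
# package's ROC/trapezoid path.
mw_auc_oracle <- function(scores, operative) {
  pos <- scores[operative]
  neg <- scores[!operative]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Raw presentation inputs realising each SITI total 0..11, verified by hand
# against the point rules (GCS bin, pupil, shift band, temporal, EDH).
total_to_presentation <- function(total) {
  stopifnot(total %in% 0:11)
  lut <- list(
    `0`  = list(15, "normal",              0,  FALSE, 0),
    `1`  = list(10, "normal",              0,  FALSE, 0),
    `2`  = list(6,  "normal",              0,  FALSE, 0),
    `3`  = list(6,  "normal",              0,  TRUE,  0),
    `4`  = list(6,  "unilateral_enlarged", 0,  FALSE, 0),
    `5`  = list(6,  "unilateral_enlarged", 0,  TRUE,  0),
    `6`  = list(6,  "unilateral_enlarged", 7,  FALSE, 0),
    `7`  = list(6,  "unilateral_enlarged", 7,  TRUE,  0),
    `8`  = list(6,  "unilateral_enlarged", 12, FALSE, 0),
    `9`  = list(6,  "unilateral_enlarged", 12, TRUE,  0),
    `10` = list(6,  "unilateral_enlarged", 12, FALSE, 12),
    `11` = list(6,  "unilateral_enlarged", 12, TRUE,  12)
  )
  p <- lut[[as.character(total)]]
  names(p) <- c("gcs_total", "pupils", "midline_shift_mm",
                "temporal_pathology", "edh_width_mm")
  p
}

# Build a labeled cohort whose SITI totals are exactly `scores`.
cohort_from_scores <- function(scores, operative) {
  stopifnot(length(scores) == length(operative))
  pres <- lapply(scores, total_to_presentation)
  siti_cohort(data.frame(
    record_id = sprintf("R%04d", seq_along(scores)),
    gcs_total = vapply(pres, `[[`, 0, "gcs_total"),
    intubated = FALSE,
    pupils = vapply(pres, `[[`, "", "pupils"),
    midline_shift_mm = vapply(pres, `[[`, 0, "midline_shift_mm"),
    temporal_pathology = vapply(pres, `[[`, TRUE, "temporal_pathology"),
    edh_width_mm = vapply(pres, `[[`, 0, "edh_width_mm"),
    operative = operative,
    exclusion_reason = "none",
    stringsAsFactors = FALSE
  ), provenance = "score-lookup test cohort")
}

# A small fully-populated cohort with optional fields and exclusions, for
# round-trip tests.
example_cohort <- function(n = 10, seed = 101, with_exclusions = FALSE) {
  spec <- cohort_spec(n_total = n, seed = seed)
  co <- generate_cohort(spec)
  if (with_exclusions && n >= 3) {
    co$exclusion_reason[1] <- "care_withdrawn"
    co$exclusion_reason[2] <- "posterior_fossa_hemorrhage"
    co$exclusion_reason[3] <- "surgery_not_considered"
    co$operative[2] <- NA
  }
  siti_cohort(as.data.frame(co), provenance = attr(co, "provenance"))
}
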