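#' @keywords internal
"_PACKAGE"

# Recognised pupil-examination categories. Bilateral enlarged and/or
# unreactive pupils are a real category (they score 0 points), not missing
# data, so the scale stays total on inputs that the source trial excluded.
PUPIL_LEVELS <- c("normal", "unilateral_enlarged", "bilateral_abnormal")

# Sanity bound on midline shift: values at or above this (in mm) are treated
# as upstream data errors rather than clinical measurements.
MAX_PLAUSIBLE_SHIFT_MM <- 50

#' SITI points for the Glasgow Coma Scale total
#'
#' A total GCS above 12 scores 0 points, 9-12 scores 1 point, and below 9
#' scores 2 points. For intubated patients the verbal component is graded
#' 1T and counted as 1 within the total; intubation itself never changes
#' the points.
#'
#' @param gcs_total Integer vector of total GCS scores, each in 3..15.
#'   Missing values propagate as `NA`.
#' @return Integer vector of points in \{0, 1, 2\}.
#' @examples
#' siti_gcs_points(c(15, 12, 9, 8, 3))
#' @export
siti_gcs_points <- function(gcs_total) {
  gcs_total <- assert_numeric_like(gcs_total, "gcs_total")
  bad <- !is.na(gcs_total) &
    (gcs_total < 3 | gcs_total > 15 | gcs_total != floor(gcs_total))
  if (any(bad)) {
    stop("gcs_total must be an integer in [3, 15]; offending value(s): ",
         paste(gcs_total[bad], collapse = ", "), call. = FALSE)
  }
  ifelse(gcs_total > 12L, 0L, ifelse(gcs_total >= 9L, 1L, 2L))
}

#' SITI points for the pupil examination
#'
#' A unilateral enlarged pupil scores 2 points. Normal exams and bilateral
#' enlarged/unreactive exams score 0. A unilaterally unreactive but not
#' enlarged pupil is not a category of the scale and should be coded
#' `"normal"`.
#'
#' @param pupils Character vector with values `"normal"`,
#'   `"unilateral_enlarged"` or `"bilateral_abnormal"`. `NA` propagates.
#' @return Integer vector of points in \{0, 2\}.
#' @examples
#' siti_pupil_points(c("normal", "unilateral_enlarged", "bilateral_abnormal"))
#' @export
siti_pupil_points <- function(pupils) {
  pupils <- as.character(pupils)
  bad <- !is.na(pupils) & !(pupils %in% PUPIL_LEVELS)
  if (any(bad)) {
    stop("unknown pupil category: ",
         paste(unique(pupils[bad]), collapse = ", "),
         " (expected one of ", paste(PUPIL_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  }
  ifelse(is.na(pupils), NA_integer_,
         ifelse(pupils == "unilateral_enlarged", 2L, 0L))
}

#' SITI points for midline shift
#'
#' Shift of the septum pellucidum, measured at the level of the foramen of
#' Monro, in millimeters. Below 5 mm scores 0, the closed band 5-10 mm
#' scores 2, and above 10 mm scores 4. Both edges of the middle band are
#' inclusive so the three bands partition the half-line.
#'
#' @param midline_shift_mm Nonnegative numeric vector, millimeters.
#'   Values at or above 50 mm are rejected as implausible.
#' @return Integer vector of points in \{0, 2, 4\}.
#' @examples
#' siti_shift_points(c(0, 4.9, 5, 10, 10.1))
#' @export
siti_shift_points <- function(midline_shift_mm) {
  x <- assert_numeric_like(midline_shift_mm, "midline_shift_mm")
  bad <- !is.na(x) & (x < 0 | x >= MAX_PLAUSIBLE_SHIFT_MM)
  if (any(bad)) {
    stop("midline_shift_mm must be in [0, ", MAX_PLAUSIBLE_SHIFT_MM,
         ") mm; offending value(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  ifelse(x > 10, 4L, ifelse(x >= 5, 2L, 0L))
}

#' SITI points for temporal pathology
#'
#' Hemorrhage or edema localized to the middle cranial fossa scores 1
#' point (herniation risk).
#'
#' @param temporal_pathology Logical vector; `NA` propagates.
#' @return Integer vector of points in \{0, 1\}.
#' @export
siti_temporal_points <- function(temporal_pathology) {
  x <- assert_logical_like(temporal_pathology, "temporal_pathology")
  ifelse(is.na(x), NA_integer_, ifelse(x, 1L, 0L))
}

#' SITI points for epidural hematoma width
#'
#' An epidural hematoma of width >= 10 mm scores 2 points; use
#' `edh_width_mm = 0` when no hematoma is present. The cutoff is inclusive
#' by default; `strict_gt = TRUE` switches to a strictly-greater-than rule.
#'
#' @param edh_width_mm Nonnegative numeric vector, millimeters.
#' @param strict_gt If `TRUE`, score 2 only when the width exceeds 10 mm.
#' @return Integer vector of points in \{0, 2\}.
#' @examples
#' siti_edh_points(c(0, 9.9, 10, 12))
#' @export
siti_edh_points <- function(edh_width_mm, strict_gt = FALSE) {
  x <- assert_numeric_like(edh_width_mm, "edh_width_mm")
  bad <- !is.na(x) & x < 0
  if (any(bad)) {
    stop("edh_width_mm must be >= 0; offending value(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  hit <- if (strict_gt) x > 10 else x >= 10
  ifelse(is.na(x), NA_integer_, ifelse(hit, 2L, 0L))
}

#' Compute the SITI score
#'
#' Applies the five component rules to one or more patient presentations
#' and returns per-component points, the additive total (0-11), and a
#' positivity flag at the given threshold. A total of 3 or more is the
#' published positivity rule.
#'
#' Any missing component makes the total and positivity `NA` for that
#' record; no imputation is done.
#'
#' @param gcs_total Integer total GCS in 3..15.
#' @param pupils Pupil category, see [siti_pupil_points()].
#' @param midline_shift_mm Midline shift in mm, see [siti_shift_points()].
#' @param temporal_pathology Logical, middle-cranial-fossa blood or edema.
#' @param edh_width_mm Epidural hematoma width in mm (0 when absent).
#' @param intubated Logical metadata flag; carried through unchanged and
#'   never alters points (the verbal score 1T is already inside
#'   `gcs_total`).
#' @param threshold Positivity threshold on the total, default 3,
#'   must be in 0..12.
#' @param edh_strict_gt Passed to [siti_edh_points()].
#' @return A data.frame of class `"siti_result"` with columns
#'   `gcs_points`, `pupil_points`, `shift_points`, `temporal_points`,
#'   `edh_points`, `total`, `positive`.
#' @examples
#' # the worst possible presentation reaches the scale maximum of 11
#' siti_score(6, "unilateral_enlarged", 12, TRUE, 12)
#' @export
siti_score <- function(gcs_total, pupils, midline_shift_mm,
                       temporal_pathology, edh_width_mm,
                       intubated = FALSE, threshold = 3L,
                       edh_strict_gt = FALSE) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 12) {
    stop("threshold must be a single integer in [0, 12]", call. = FALSE)
  }
  n <- max(length(gcs_total), length(pupils), length(midline_shift_mm),
           length(temporal_pathology), length(edh_width_mm))
  res <- data.frame(
    gcs_points      = rep_len(siti_gcs_points(gcs_total), n),
    pupil_points    = rep_len(siti_pupil_points(pupils), n),
    shift_points    = rep_len(siti_shift_points(midline_shift_mm), n),
    temporal_points = rep_len(siti_temporal_points(temporal_pathology), n),
    edh_points      = rep_len(siti_edh_points(edh_width_mm,
                                              strict_gt = edh_strict_gt), n)
  )
  res$total <- res$gcs_points + res$pupil_points + res$shift_points +
    res$temporal_points + res$edh_points
  res$positive <- res$total >= threshold
  attr(res, "threshold") <- as.integer(threshold)
  class(res) <- c("siti_result", class(res))
  res
}

#' Enumerate every SITI component-level combination
#'
#' Exhaustively crosses the component levels — GCS bin (>12, 9-12, <9),
#' the three pupil categories, the three midline-shift bands, temporal
#' pathology yes/no, epidural hematoma at/above cutoff yes/no — and scores
#' a representative presentation for each of the 3*3*3*2*2 = 108
#' combinations through [siti_score()]. The table is an exhaustive oracle
#' for the scale: totals span exactly 0..11 (the three pupil categories
#' collapse to two point levels, so 72 distinct point patterns remain).
#'
#' @return A data.frame with one row per combination: the five component
#'   point columns, the pupil category, and `total`.
#' @examples
#' rng <- range(siti_enumerate()$total)  # 0 and 11
#' @export
siti_enumerate <- function() {
  grid <- expand.grid(
    gcs_bin    = c("gt12", "9-12", "lt9"),
    pupils     = PUPIL_LEVELS,
    shift_band = c("lt5", "5-10", "gt10"),
    temporal   = c(FALSE, TRUE),
    edh        = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # representative raw inputs realising each level
  gcs_rep   <- c(gt12 = 15L, `9-12` = 10L, lt9 = 6L)
  shift_rep <- c(lt5 = 0, `5-10` = 7, gt10 = 12)
  scored <- siti_score(
    gcs_total          = gcs_rep[grid$gcs_bin],
    pupils             = grid$pupils,
    midline_shift_mm   = shift_rep[grid$shift_band],
    temporal_pathology = grid$temporal,
    edh_width_mm       = ifelse(grid$edh, 12, 0)
  )
  out <- cbind(pupils = grid$pupils,
               as.data.frame(scored)[c("gcs_points", "pupil_points",
                                       "shift_points", "temporal_points",
                                       "edh_points", "total")])
  rownames(out) <- NULL
  out
}

# ---- input coercion helpers -------------------------------------------------

assert_numeric_like <- function(x, name) {
  if (is.logical(x) && all(is.na(x))) return(as.numeric(x))
  if (!is.numeric(x)) {
    stop(name, " must be numeric, got ", class(x)[1], call. = FALSE)
  }
  as.numeric(x)
}

assert_logical_like <- function(x, name) {
  if (is.numeric(x)) {
    if (any(!is.na(x) & !(x %in% c(0, 1)))) {
      stop(name, " must be logical or 0/1", call. = FALSE)
    }
    return(x == 1)
  }
  if (!is.logical(x)) {
    stop(name, " must be logical or 0/1, got ", class(x)[1], call. = FALSE)
  }
  x
}
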