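# Labeled patient cohorts: CSV schema, validation, exclusion accounting.
#
# Schema (columns, in order): record_id, gcs_total, intubated, pupils,
# midline_shift_mm, temporal_pathology, edh_width_mm, operative,
# exclusion_reason, age_years, transport_minutes, mechanism.
# First eight required, last four optional. Comma-separated, UTF-8, header
# row mandatory, "." decimal separator, booleans serialized as 0/1,
# missing values as empty cells, pupil categories as literal tokens.

COHORT_REQUIRED_COLS <- c("record_id", "gcs_total", "intubated", "pupils",
                          "midline_shift_mm", "temporal_pathology",
                          "edh_width_mm", "operative", "exclusion_reason")
COHORT_OPTIONAL_COLS <- c("age_years", "transport_minutes", "mechanism")
EXCLUSION_LEVELS <- c("none", "care_withdrawn", "posterior_fossa_hemorrhage",
                      "surgery_not_considered")

#' Construct a labeled SITI cohort
#'
#' Builds and validates the cohort container used by every evaluation
#' operation: one row per patient presentation together with the operative
#' label (craniotomy or craniectomy within 24 h of arrival) and an
#' exclusion flag.
#'
#' @param records A data.frame with at least the nine required schema
#'   columns (`record_id`, `gcs_total`, `intubated`, `pupils`,
#'   `midline_shift_mm`, `temporal_pathology`, `edh_width_mm`,
#'   `operative`, `exclusion_reason`); missing optional columns
#'   (`age_years`, `transport_minutes`, `mechanism`) are added as `NA`.
#' @param provenance Free-text note on where the records came from.
#' @param strict If `TRUE` (default), any invalid row aborts with its row
#'   number and field; if `FALSE`, invalid rows are dropped with a message
#'   and their count kept in `attr(, "n_dropped")`.
#' @return A data.frame of class `"siti_cohort"`.
#' @export
siti_cohort <- function(records, provenance = "constructed in R",
                        strict = TRUE) {
  if (!is.data.frame(records)) {
    stop("records must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in COHORT_OPTIONAL_COLS) {
    if (is.null(records[[col]])) {
      records[[col]] <- if (col == "mechanism") NA_character_ else NA_real_
    }
  }
  records <- records[c(COHORT_REQUIRED_COLS, COHORT_OPTIONAL_COLS)]
  records$record_id <- as.character(records$record_id)
  records$pupils <- as.character(records$pupils)
  records$exclusion_reason <- as.character(records$exclusion_reason)
  records$exclusion_reason[is.na(records$exclusion_reason)] <- "none"
  records$mechanism <- as.character(records$mechanism)
  for (col in c("intubated", "temporal_pathology", "operative")) {
    records[[col]] <- coerce_01_logical(records[[col]], col)
  }
  for (col in c("gcs_total", "midline_shift_mm", "edh_width_mm",
                "age_years", "transport_minutes")) {
    records[[col]] <- coerce_cohort_numeric(records[[col]], col)
  }

  problems <- validate_cohort_rows(records)
  if (length(problems) > 0) {
    if (strict) {
      stop("invalid cohort row(s):\n  ",
           paste(vapply(problems, `[[`, "", "message"), collapse = "\n  "),
           call. = FALSE)
    }
    bad_rows <- unique(vapply(problems, `[[`, 0L, "row"))
    message("dropping ", length(bad_rows), " invalid row(s) of ",
            nrow(records))
    records <- records[-bad_rows, , drop = FALSE]
    rownames(records) <- NULL
  }
  n_dropped <- if (length(problems) > 0) {
    length(unique(vapply(problems, `[[`, 0L, "row")))
  } else 0L

  structure(records,
            provenance = provenance,
            n_dropped = n_dropped,
            class = c("siti_cohort", "data.frame"))
}

# Per-row schema checks; returns a list of (row, field, message).
validate_cohort_rows <- function(d) {
  problems <- list()
  note <- function(rows, field, why) {
    for (r in rows) {
      problems[[length(problems) + 1L]] <<- list(
        row = r, field = field,
        message = sprintf("row %d, field %s: %s", r, field, why))
    }
  }
  dup <- duplicated(d$record_id) | is.na(d$record_id) | d$record_id == ""
  note(which(dup), "record_id", "missing or duplicated id")
  g <- d$gcs_total
  note(which(!is.na(g) & (g < 3 | g > 15 | g != floor(g))),
       "gcs_total", "must be an integer in [3, 15]")
  note(which(!is.na(d$pupils) & !(d$pupils %in% PUPIL_LEVELS)),
       "pupils", paste("must be one of", paste(PUPIL_LEVELS, collapse = ", ")))
  s <- d$midline_shift_mm
  note(which(!is.na(s) & (s < 0 | s >= MAX_PLAUSIBLE_SHIFT_MM)),
       "midline_shift_mm",
       sprintf("must be in [0, %d) mm", MAX_PLAUSIBLE_SHIFT_MM))
  note(which(!is.na(d$edh_width_mm) & d$edh_width_mm < 0),
       "edh_width_mm", "must be >= 0")
  note(which(!(d$exclusion_reason %in% EXCLUSION_LEVELS)),
       "exclusion_reason",
       paste("must be one of", paste(EXCLUSION_LEVELS, collapse = ", ")))
  note(which(is.na(d$operative) & d$exclusion_reason == "none"),
       "operative", "may be missing only for excluded records")
  note(which(!is.na(d$age_years) & d$age_years < 0), "age_years",
       "must be >= 0")
  note(which(!is.na(d$transport_minutes) & d$transport_minutes < 0),
       "transport_minutes", "must be >= 0")
  problems
}

#' Read a labeled cohort from CSV
#'
#' Reads and validates a cohort in the documented schema (see
#' [siti_cohort()] for the column list and [write_cohort()] for the
#' serialization conventions).
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default) any invalid row aborts with its row
#'   number and field; if `FALSE` invalid rows are dropped with a message.
#' @return A `"siti_cohort"` data.frame; `attr(, "n_dropped")` counts rows
#'   dropped in lenient mode.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         na.strings = "")
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("gcs_total", "midline_shift_mm", "edh_width_mm",
                "age_years", "transport_minutes")) {
    if (!is.null(raw[[col]])) {
      val <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(val))
      if (length(bad) > 0 && strict) {
        stop("row ", bad[1], ", field ", col, ": unparseable numeric '",
             raw[[col]][bad[1]], "'", call. = FALSE)
      }
      raw[[col]] <- val
    }
  }
  for (col in c("intubated", "temporal_pathology", "operative")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  siti_cohort(raw, provenance = path, strict = strict)
}

#' Write a labeled cohort to CSV
#'
#' Serializes a cohort in the documented schema: comma-separated, UTF-8,
#' header row, booleans as 0/1, missing values as empty cells. Reading the
#' file back with [read_cohort()] reproduces the cohort field-for-field.
#'
#' @param cohort A `"siti_cohort"` (or conforming data.frame).
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as.data.frame(siti_cohort(cohort, provenance = "write"))
  for (col in c("intubated", "temporal_pathology", "operative")) {
    cohort[[col]] <- ifelse(is.na(cohort[[col]]), NA_integer_,
                            as.integer(cohort[[col]]))
  }
  ok <- tryCatch({
    utils::write.csv(cohort, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write cohort to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Apply the exclusion flow to a cohort
#'
#' Removes records flagged with an exclusion reason (care withdrawn,
#' posterior fossa hemorrhage, surgery not considered / medically unfit)
#' and tallies each reason, mirroring the enrolled-to-assessed flow of a
#' retrospective review. The assessed size always equals the input size
#' minus the tally sum, and the operation is idempotent.
#'
#' @param cohort A `"siti_cohort"`.
#' @return A list with elements `cohort` (assessed records only, exclusion
#'   reason `"none"`), `tally` (named integer vector over the three
#'   exclusion reasons), `n_input` and `n_assessed`.
#' @export
apply_exclusions <- function(cohort) {
  cohort <- siti_cohort(cohort, provenance = attr(cohort, "provenance"))
  reasons <- setdiff(EXCLUSION_LEVELS, "none")
  tally <- vapply(reasons, function(r) sum(cohort$exclusion_reason == r), 0L)
  kept <- cohort[cohort$exclusion_reason == "none", , drop = FALSE]
  rownames(kept) <- NULL
  stopifnot(nrow(kept) + sum(tally) == nrow(cohort))
  list(cohort = kept, tally = tally,
       n_input = nrow(cohort), n_assessed = nrow(kept))
}

#' Score every record of a cohort
#'
#' @param cohort A `"siti_cohort"`.
#' @param threshold,edh_strict_gt See [siti_score()].
#' @return The cohort with the seven [siti_score()] columns appended.
#' @export
score_cohort <- function(cohort, threshold = 3L, edh_strict_gt = FALSE) {
  cohort <- siti_cohort(cohort, provenance = attr(cohort, "provenance"))
  scores <- siti_score(cohort$gcs_total, cohort$pupils,
                       cohort$midline_shift_mm, cohort$temporal_pathology,
                       cohort$edh_width_mm, intubated = cohort$intubated,
                       threshold = threshold, edh_strict_gt = edh_strict_gt)
  out <- cbind(as.data.frame(cohort), as.data.frame(scores))
  attr(out, "threshold") <- as.integer(threshold)
  out
}

#' @export
print.siti_cohort <- function(x, ...) {
  cat(sprintf("SITI labeled cohort: %d record(s) (%s)\n", nrow(x),
              attr(x, "provenance")))
  n_op <- sum(x$operative, na.rm = TRUE)
  n_ex <- sum(x$exclusion_reason != "none")
  cat(sprintf("  operative: %d, nonoperative: %d, flagged for exclusion: %d\n",
              n_op, sum(!x$operative, na.rm = TRUE), n_ex))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5), ...)
  invisible(x)
}

coerce_01_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (any(!is.na(x) & !(x %in% c(0, 1)))) {
      stop("column ", name, " must be logical or 0/1", call. = FALSE)
    }
    return(x == 1)
  }
  if (is.character(x)) {
    low <- tolower(x)
    val <- ifelse(is.na(low), NA,
                  ifelse(low %in% c("1", "true", "t"), TRUE,
                         ifelse(low %in% c("0", "false", "f"), FALSE, NA)))
    bad <- !is.na(x) & is.na(val)
    if (any(bad)) {
      stop("column ", name, " has non-boolean value(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    return(val)
  }
  stop("column ", name, " must be logical or 0/1", call. = FALSE)
}

coerce_cohort_numeric <- function(x, name) {
  if (is.logical(x) && all(is.na(x))) return(as.numeric(x))
  if (!is.numeric(x)) {
    stop("column ", name, " must be numeric", call. = FALSE)
  }
  as.numeric(x)
}
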