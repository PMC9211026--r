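#' Read a long-format measurement table
#'
#' Reads the tab- (or comma-) separated contract consumed by the
#' pipeline: columns `subject_id`, `group`, `visit_date` (ISO-8601),
#' `roi_id`, `measure`, `stream`, `value`. Validation errors name the
#' offending file line (header = line 1). Duplicate
#' (subject, visit, ROI, measure) rows and non-positive values are
#' rejected: both indicate an upstream extraction fault that should be
#' fixed, not silently analysed.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @return Validated tibble with `visit_date` as `Date`.
#' @export
read_measurements <- function(path) {
  tbl <- read_delim_auto(path)
  needed <- c("subject_id", "group", "visit_date", "roi_id", "measure",
              "stream", "value")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  line_of <- function(i) i + 1L  # header occupies line 1

  dates <- as.Date(as.character(tbl$visit_date),
                   format = "%Y-%m-%d", optional = TRUE)
  bad_date <- which(is.na(dates))
  if (length(bad_date) > 0) {
    abort(paste0(path, " line ", line_of(bad_date[1]),
                 ": unparseable visit_date \"",
                 tbl$visit_date[bad_date[1]], "\" (expected YYYY-MM-DD)."))
  }
  vals <- suppressWarnings(as.numeric(tbl$value))
  bad_val <- which(is.na(vals) | vals <= 0)
  if (length(bad_val) > 0) {
    abort(paste0(path, " line ", line_of(bad_val[1]),
                 ": value \"", tbl$value[bad_val[1]],
                 "\" is not a strictly positive number."))
  }
  tbl <- mutate(tbl, visit_date = dates, value = vals)

  dup <- duplicated(tbl[c("subject_id", "visit_date", "roi_id", "measure")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0(path, " line ", line_of(i), ": duplicate record for ",
                 tbl$subject_id[i], " / ", tbl$visit_date[i], " / ",
                 tbl$roi_id[i], " / ", tbl$measure[i], "."))
  }
  tbl
}

#' Write a measurement table in the pipeline's TSV contract
#'
#' Tab-separated, UTF-8, `.` decimal separator, dates ISO-8601, full
#' numeric precision. [read_measurements()] on the written file
#' round-trips the table.
#'
#' @param measurements Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- mutate(as_tibble(measurements),
                visit_date = format(as.Date(.data$visit_date), "%Y-%m-%d"),
                value = format_full(.data$value))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a long-format cognitive score table
#'
#' Columns `subject_id`, `group` (optional), `visit`
#' (`screening`/`year1`), `instrument`, `score`.
#'
#' @param path Path to a `.tsv`/`.txt` or `.csv` file.
#' @return Validated tibble.
#' @export
read_cognition <- function(path) {
  tbl <- read_delim_auto(path)
  needed <- c("subject_id", "visit", "instrument", "score")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  bad <- which(!tbl$visit %in% c("screening", "year1"))
  if (length(bad) > 0) {
    abort(paste0(path, " line ", bad[1] + 1L, ": visit \"",
                 tbl$visit[bad[1]], "\" is not screening/year1."))
  }
  mutate(tbl, score = as.numeric(.data$score))
}

#' @rdname read_cognition
#' @param cognition Cognitive score tibble.
#' @export
write_cognition <- function(cognition, path) {
  out <- mutate(as_tibble(cognition), score = format_full(.data$score))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic cohort
#'
#' Long TSV with one row per group x feature:
#' `roi_id  measure  group  q_true  is_null`.
#'
#' @param truth The `truth` element of [generate_cohort()] output.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  feats <- truth$features
  long <- bind_rows(
    tibble(roi_id = feats$roi_id, measure = feats$measure,
           group = "case", q_true = feats$q_true_case,
           is_null = feats$is_null),
    tibble(roi_id = feats$roi_id, measure = feats$measure,
           group = "control", q_true = feats$q_true_ctrl,
           is_null = feats$is_null)
  )
  readr::write_tsv(mutate(long, q_true = format_full(.data$q_true)), path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
}

# full double precision, no scientific notation surprises on re-read
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}
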