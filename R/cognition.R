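#' Per-subject cognitive score changes
#'
#' Computes `year1 - screening` per subject and instrument as a raw
#' difference in instrument units. A percent-change formulation is
#' deliberately avoided: CDR, FAQ and NPI are legitimately 0 at
#' baseline, where a relative change is undefined. Subjects missing
#' either visit for an instrument are dropped listwise for that
#' instrument (not globally) with a warning giving the count.
#'
#' @param cognition Long tibble `subject_id`, `visit`
#'   (`"screening"`/`"year1"`), `instrument`, `score`; a `group`
#'   column, if present, is carried through.
#' @return Tibble `subject_id` (, `group`), `instrument`, `delta`.
#' @export
score_change <- function(cognition) {
  cognition <- as_tibble(cognition)
  needed <- c("subject_id", "visit", "instrument", "score")
  missing_cols <- setdiff(needed, names(cognition))
  if (length(missing_cols) > 0) {
    abort(paste0("`cognition` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!all(cognition$visit %in% c("screening", "year1"))) {
    abort("`visit` must be \"screening\" or \"year1\".")
  }
  carry <- intersect("group", names(cognition))
  wide <- cognition |>
    tidyr::pivot_wider(id_cols = all_of(c("subject_id", carry, "instrument")),
                       names_from = "visit", values_from = "score")
  if (!all(c("screening", "year1") %in% names(wide))) {
    wide$screening <- wide$screening %||% NA_real_
    wide$year1 <- wide$year1 %||% NA_real_
  }
  incomplete <- !complete.cases(wide[c("screening", "year1")])
  if (any(incomplete)) {
    warn(paste0("Dropped ", sum(incomplete), " subject x instrument ",
                "record(s) missing a visit."))
  }
  wide |>
    filter(!incomplete) |>
    mutate(delta = .data$year1 - .data$screening) |>
    select(all_of(c("subject_id", carry, "instrument", "delta")))
}

#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of the two variables' average ranks (ties get
#' the mean of the ranks they span). Invariant under strictly monotone
#' transforms of either variable. A constant input vector leaves the
#' correlation undefined; `NA` is returned with a warning rather than
#' an error so that a single flat region does not abort a whole scan
#' over features.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Single numeric rho in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input vector: Spearman correlation undefined.")
    return(NA_real_)
  }
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Correlate regional APC values with cognitive change
#'
#' For every ROI x measure x instrument, computes the Spearman rank
#' correlation between subjects' APC values and their cognitive score
#' change over the pooled subject set (cases and controls together --
#' pooling spans the full severity range and is what gives the
#' morphometry-cognition association its resolution; restrict
#' `subjects` to analyse one group). Combinations with fewer than
#' `min_n` overlapping subjects are omitted with a warning.
#'
#' @param apc_tbl APC table from [apc_table()].
#' @param deltas Score-change table from [score_change()].
#' @param instruments Optional character vector restricting the
#'   instruments analysed.
#' @param subjects Optional character vector of subject ids to keep
#'   (e.g. the QA-retained set).
#' @param min_n Minimum overlapping subjects per correlation
#'   (default 3).
#' @return Tibble `roi_id`, `measure`, `stream`, `instrument`, `rho`,
#'   `n`.
#' @export
correlate_rois <- function(apc_tbl, deltas, instruments = NULL,
                           subjects = NULL, min_n = 3) {
  apc_tbl <- as_tibble(apc_tbl)
  deltas <- as_tibble(deltas)
  if (!is.null(instruments)) {
    deltas <- filter(deltas, .data$instrument %in% instruments)
  }
  if (!is.null(subjects)) {
    apc_tbl <- filter(apc_tbl, .data$subject_id %in% subjects)
    deltas <- filter(deltas, .data$subject_id %in% subjects)
  }
  joined <- inner_join(
    select(apc_tbl, "subject_id", "roi_id", "measure", "stream", "apc"),
    select(deltas, "subject_id", "instrument", "delta"),
    by = "subject_id", relationship = "many-to-many"
  )
  if (nrow(joined) == 0) {
    warn("No overlapping subjects between the APC and cognition tables.")
    return(tibble(roi_id = character(), measure = character(),
                  stream = character(), instrument = character(),
                  rho = numeric(), n = integer()))
  }
  out <- joined |>
    group_by(.data$roi_id, .data$measure, .data$stream, .data$instrument) |>
    summarise(
      n = n(),
      rho = if (n() >= min_n) suppressWarnings(spearman_rho(.data$apc,
                                                            .data$delta))
            else NA_real_,
      .groups = "drop"
    )
  dropped <- sum(out$n < min_n)
  if (dropped > 0) {
    warn(paste0("Omitted ", dropped, " combination(s) with fewer than ",
                min_n, " overlapping subjects."))
  }
  out |>
    filter(.data$n >= min_n) |>
    select("roi_id", "measure", "stream", "instrument", "rho", "n")
}
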