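#' Relative change between two strictly positive measurements
#'
#' The dimensionless relative change `(x2 - x1) / x1`. Both measurements
#' must be strictly positive: morphometric features (volumes, areas,
#' thicknesses) are strictly positive quantities and a non-positive
#' baseline leaves the ratio undefined.
#'
#' @param x1,x2 Numeric vectors of measurements at the first and second
#'   visit, in the same units. Recycled to a common length.
#' @return Numeric vector of relative changes.
#' @examples
#' relative_change(100, 95) # -0.05
#' @export
relative_change <- function(x1, x2) {
  check_positive(x1, "x1")
  check_positive(x2, "x2")
  (x2 - x1) / x1
}

#' Per-unit-time growth rate under the multiplicative change model
#'
#' Under an exponential growth/decay model `x(t) = x0 * (1 + q)^t`, two
#' observations determine the rate per unit of `t`:
#' `q = (x2 / x1)^(1 / (t2 - t1)) - 1`. With timepoints in days this is a
#' daily rate; `q > -1` always, so projected values stay positive.
#'
#' @inheritParams relative_change
#' @param t1,t2 Timepoints (days); `t2 > t1` elementwise.
#' @return Numeric vector of rates per day.
#' @examples
#' annual_rate(100, 90.25, 0, 2) # -0.05 per unit
#' @export
annual_rate <- function(x1, x2, t1, t2) {
  check_positive(x1, "x1")
  check_positive(x2, "x2")
  dt <- t2 - t1
  if (any(dt <= 0)) {
    abort("`t2` must be strictly greater than `t1` for every observation.")
  }
  (x2 / x1)^(1 / dt) - 1
}

#' Annual percent change (APC)
#'
#' Normalizes an observed change to a nominal observation interval of
#' `n` days under the multiplicative model:
#' `APC = ((x2 / x1)^(n / (t2 - t1)) - 1) * 100`.
#' When the actual interval equals `n` this collapses to
#' `100 * relative_change()`. Because subjects rarely return exactly
#' `n` days after baseline, this correction removes the interval
#' variation that would otherwise inflate between-subject variance.
#' APC is bounded below by -100 for valid (positive) inputs.
#'
#' @inheritParams annual_rate
#' @param n_days Normalization interval in days; 365 for an annual
#'   change. Studies with a different follow-up design (say 180 days)
#'   set `n_days` accordingly.
#' @return Numeric vector of percent changes per `n_days`-day period.
#' @examples
#' apc(100, 95, 0, 365)      # -5, interval matches the year
#' apc(100, 95, 0, 730)      # about -2.53, two-year interval annualized
#' @export
apc <- function(x1, x2, t1, t2, n_days = 365) {
  if (any(n_days <= 0)) abort("`n_days` must be strictly positive.")
  q <- annual_rate(x1, x2, t1, t2)
  ((1 + q)^n_days - 1) * 100
}

#' Project a value forward under the multiplicative model
#'
#' `project(x0, q, t) = x0 * (1 + q)^t`: the exponential growth/decay
#' model itself. Strictly positive for every `t` whenever `x0 > 0` and
#' `q > -1`, which is what makes the model admissible for strictly
#' positive quantities such as brain volumes.
#'
#' @param x0 Starting value, strictly positive.
#' @param q Rate per unit of `t`; must exceed -1.
#' @param t Time (same unit as `q`'s denominator); may be negative.
#' @return Projected value, strictly positive.
#' @seealso [linear_projection()] for the additive model this one replaces.
#' @export
project <- function(x0, q, t) {
  check_positive(x0, "x0")
  if (any(q <= -1)) abort("`q` must be greater than -1.")
  x0 * (1 + q)^t
}

#' Linear (additive) projection: the documented counterexample
#'
#' Some longitudinal analyses normalize change linearly,
#' `x(t) = x1 + P * x1 * t` with `P = (x2 - x1) / (x1 * (t2 - t1))`.
#' Dividing by the interval assumes the absolute change per day is
#' constant, which drives `x(t)` below zero for large `t` whenever
#' `x2 < x1` -- impossible for a volume. The function exists to
#' demonstrate that failure; the pipeline never uses it.
#'
#' @inheritParams annual_rate
#' @param t Time in the same unit as `t2 - t1`, measured from `t1`.
#' @return Projected value; may be zero or negative.
#' @examples
#' linear_projection(100, 50, 0, 1, t = 3) # -50: impossible for a volume
#' @export
linear_projection <- function(x1, x2, t1, t2, t) {
  check_positive(x1, "x1")
  check_positive(x2, "x2")
  dt <- t2 - t1
  if (any(dt <= 0)) {
    abort("`t2` must be strictly greater than `t1` for every observation.")
  }
  p_rate <- (x2 - x1) / (x1 * dt)
  x1 + p_rate * x1 * t
}

#' Annualize a two-visit measurement table
#'
#' Converts a long measurement table (one row per subject, visit, ROI
#' and measure) into one APC record per subject x ROI x measure.
#' Visits are identified by date order: the earlier date is baseline.
#' Every subject x ROI x measure triple must have exactly two visits.
#' Records with a non-positive value are dropped with a warning giving
#' the count (degenerate region extractions do occur in practice and
#' should not abort a whole study); subjects whose observed interval
#' deviates from `n_days` by more than `warn_frac * n_days` are flagged
#' with a warning, since the constant-rate assumption weakens as the
#' deviation grows.
#'
#' @param measurements Data frame with columns `subject_id`, `group`,
#'   `visit_date` (Date or ISO-8601 string), `roi_id`, `measure`,
#'   `stream`, `value`.
#' @param n_days Normalization interval in days (default 365).
#' @param warn_frac Fraction of `n_days` beyond which an observed
#'   interval triggers a warning (default 0.5).
#' @return Tibble with one row per subject x ROI x measure:
#'   `subject_id`, `group`, `roi_id`, `measure`, `stream`,
#'   `delta_days`, `rc` (relative change), `q_day` (daily rate),
#'   `apc` (percent per `n_days`).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_per_group = 3,
#'   roi_spec = tibble::tibble(roi_id = "L_Hippocampus",
#'                             measure = "volume", stream = "vbm"),
#'   noise_sigma = 0, seed = 1
#' ))
#' apc_table(cohort$measurements)
#' @export
apc_table <- function(measurements, n_days = 365, warn_frac = 0.5) {
  measurements <- as_tibble(measurements)
  needed <- c("subject_id", "group", "visit_date", "roi_id", "measure",
              "stream", "value")
  missing_cols <- setdiff(needed, names(measurements))
  if (length(missing_cols) > 0) {
    abort(paste0("`measurements` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(measurements) == 0) {
    return(tibble(
      subject_id = character(), group = character(), roi_id = character(),
      measure = character(), stream = character(), delta_days = numeric(),
      rc = numeric(), q_day = numeric(), apc = numeric()
    ))
  }
  measurements <- mutate(measurements, visit_date = as.Date(.data$visit_date))

  counts <- count(measurements,
                  .data$subject_id, .data$roi_id, .data$measure, .data$stream)
  bad <- filter(counts, .data$n != 2L)
  if (nrow(bad) > 0) {
    offenders <- head(
      paste0(bad$subject_id, "/", bad$roi_id, "/", bad$measure,
             " (", bad$n, " visits)"), 5L)
    abort(paste0(
      nrow(bad), " subject x ROI x measure triple(s) do not have exactly ",
      "two visits, e.g. ", paste(offenders, collapse = "; "), "."))
  }

  n_nonpos <- sum(measurements$value <= 0)
  if (n_nonpos > 0) {
    dropped <- filter(measurements, .data$value <= 0)
    dropped_keys <- distinct(dropped, .data$subject_id, .data$roi_id,
                             .data$measure, .data$stream)
    measurements <- anti_join(
      measurements, dropped_keys,
      by = c("subject_id", "roi_id", "measure", "stream"))
    warn(paste0("Dropped ", nrow(dropped_keys), " record(s) containing ",
                n_nonpos, " non-positive value(s)."))
  }

  out <- measurements |>
    arrange(.data$subject_id, .data$roi_id, .data$measure, .data$stream,
            .data$visit_date) |>
    group_by(.data$subject_id, .data$group, .data$roi_id, .data$measure,
             .data$stream) |>
    summarise(
      delta_days = as.numeric(.data$visit_date[2] - .data$visit_date[1]),
      x1 = .data$value[1],
      x2 = .data$value[2],
      .groups = "drop"
    )
  if (any(out$delta_days <= 0)) {
    abort("Found a subject with two visits on the same date.")
  }

  out <- out |>
    mutate(
      rc = relative_change(.data$x1, .data$x2),
      q_day = annual_rate(.data$x1, .data$x2, 0, .data$delta_days),
      apc = apc(.data$x1, .data$x2, 0, .data$delta_days, n_days = n_days)
    ) |>
    select(-"x1", -"x2")

  stray <- distinct(filter(out, abs(.data$delta_days - n_days) >
                             warn_frac * n_days), .data$subject_id)
  if (nrow(stray) > 0) {
    warn(paste0(nrow(stray), " subject(s) have an observation interval ",
                "deviating from ", n_days, " days by more than ",
                warn_frac * 100, "%: ",
                paste(head(stray$subject_id, 5L), collapse = ", "),
                ". The constant-rate assumption may not hold for them."))
  }
  out
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be finite and strictly positive."))
  }
  invisible(x)
}
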