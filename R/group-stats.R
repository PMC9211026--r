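#' Two-sample t-test from group summary statistics
#'
#' Computes the two-sided two-sample t-test directly from per-group
#' means, standard deviations and sizes -- the form needed to audit a
#' published comparison table where only summaries are printed. The
#' default pooled (Student) variant assumes equal variances with
#' `df = n_a + n_b - 2`; `variant = "welch"` uses the Welch-Satterthwaite
#' approximation instead. When both SDs are zero and the means are
#' equal the test is defined as `t = 0, p = 1` (no evidence of a
#' difference); zero SDs with unequal means give `p = 0` and a warning
#' about the degenerate variance.
#'
#' @param mean_a,sd_a,n_a Summary statistics of the first group.
#' @param mean_b,sd_b,n_b Summary statistics of the second group.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return Tibble with columns `t`, `df`, `p` (one row per input
#'   element; the summaries are vectorized).
#' @examples
#' ttest_from_summary(-3.87, 3.94, 25, 0.43, 3.94, 25)  # p ~ 0.0003
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (any(n_a < 2) || any(n_b < 2)) {
    abort("Both groups need at least 2 observations.")
  }
  if (any(sd_a < 0) || any(sd_b < 0)) {
    abort("Standard deviations must be non-negative.")
  }
  if (variant == "pooled") {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  diff <- mean_a - mean_b
  t_stat <- ifelse(se == 0 & diff == 0, 0, diff / se)
  if (any(se == 0 & diff != 0)) {
    warn("Zero within-group variance with unequal means: p collapses to 0.")
    df[se == 0 & diff != 0] <- n_a + n_b - 2
  }
  p <- ifelse(is.infinite(t_stat) | (se == 0 & diff != 0), 0,
              2 * pt(-abs(t_stat), df))
  tibble(t = as.numeric(t_stat), df = as.numeric(df), p = as.numeric(p))
}

#' Two-sample t-test from raw values
#'
#' Raw-data path for synthetic cohorts; defined to agree with
#' [ttest_from_summary()] applied to the samples' means, SDs and sizes
#' to machine precision.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @inheritParams ttest_from_summary
#' @return One-row tibble `t`, `df`, `p`.
#' @export
ttest_from_values <- function(values_a, values_b,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Both groups need at least 2 values.")
  }
  ttest_from_summary(mean(values_a), sd(values_a), length(values_a),
                     mean(values_b), sd(values_b), length(values_b),
                     variant = variant)
}

#' Per-feature two-group comparison of APC values
#'
#' For every ROI x measure, summarises the APC distribution in the case
#' and control groups and tests the group difference with a two-sample
#' t-test. Rows are returned sorted by ascending p-value, with an
#' uncorrected significance flag at `alpha` (individual testing level);
#' multiplicity correction is a separate step ([correct_mtc()]).
#'
#' @param apc_tbl APC table from [apc_table()] (needs `subject_id`,
#'   `group`, `roi_id`, `measure`, `stream`, `apc`).
#' @param case,control Group labels; default the first and second
#'   label in sorted order.
#' @inheritParams ttest_from_summary
#' @param alpha Two-sided level for the uncorrected flag (default 0.05).
#' @return Tibble (class `apc_comparison`) with one row per
#'   ROI x measure: `roi_id`, `measure`, `stream`, `mean_a`, `sd_a`,
#'   `n_a` (case), `mean_b`, `sd_b`, `n_b` (control), `t`, `df`, `p`,
#'   `sig_unc`. Group labels are kept in attributes `case`/`control`.
#' @export
compare_all <- function(apc_tbl, case = NULL, control = NULL,
                        variant = c("pooled", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  apc_tbl <- as_tibble(apc_tbl)
  levels <- sort(unique(apc_tbl$group))
  case <- case %||% levels[1]
  control <- control %||% setdiff(levels, case)[1]
  if (!case %in% levels || !control %in% levels || is.na(control)) {
    abort(paste0("Groups `", case, "` and `", control,
                 "` must both be present in `apc_tbl$group`."))
  }

  summaries <- apc_tbl |>
    filter(.data$group %in% c(case, control)) |>
    group_by(.data$roi_id, .data$measure, .data$stream, .data$group) |>
    summarise(mean = mean(.data$apc), sd = sd(.data$apc), n = n(),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("mean", "sd", "n"))
  col <- function(prefix, g) summaries[[paste0(prefix, "_", g)]]
  out <- tibble(
    roi_id = summaries$roi_id, measure = summaries$measure,
    stream = summaries$stream,
    mean_a = col("mean", case), sd_a = col("sd", case), n_a = col("n", case),
    mean_b = col("mean", control), sd_b = col("sd", control),
    n_b = col("n", control)
  )
  if (anyNA(out$n_a) || anyNA(out$n_b) ||
      any(out$n_a < 2) || any(out$n_b < 2)) {
    abort("Every ROI x measure needs at least 2 subjects per group.")
  }
  tt <- ttest_from_summary(out$mean_a, out$sd_a, out$n_a,
                           out$mean_b, out$sd_b, out$n_b, variant = variant)
  out <- out |>
    mutate(t = tt$t, df = tt$df, p = tt$p, sig_unc = tt$p < alpha) |>
    arrange(.data$p, .data$roi_id, .data$measure)
  structure(out, class = c("apc_comparison", class(out)),
            case = case, control = control, variant = variant,
            alpha = alpha)
}

#' Overlap between two groups' APC distributions
#'
#' Quantifies how separable two groups are from region-level mean APC
#' values alone (the overlaid-histogram view of a cohort). Both samples
#' are binned on a shared fixed-width grid spanning their joint range;
#' each histogram is normalized to a density, and the overlap
#' coefficient is `sum(min(f_a, f_b)) * width`, which is 1 for
#' identical distributions and 0 for disjoint ones. A fixed bin width
#' (default 0.5 APC percentage points) keeps the coefficient
#' reproducible across cohorts.
#'
#' @param means_a,means_b Numeric vectors of region-level group-mean
#'   APC values (length >= 2 each).
#' @param bin_width Histogram bin width in APC percentage points.
#' @return Object of class `overlap_summary`: list with `breaks`,
#'   `density_a`, `density_b`, `overlap`, `bin_width`.
#' @export
distribution_overlap <- function(means_a, means_b, bin_width = 0.5) {
  if (length(means_a) < 2 || length(means_b) < 2) {
    abort("Both samples need at least 2 values.")
  }
  if (bin_width <= 0) abort("`bin_width` must be strictly positive.")
  lo <- floor(min(means_a, means_b) / bin_width) * bin_width
  hi <- ceiling(max(means_a, means_b) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  f_a <- graphics::hist(means_a, breaks = breaks, plot = FALSE)$density
  f_b <- graphics::hist(means_b, breaks = breaks, plot = FALSE)$density
  structure(
    list(breaks = breaks, density_a = f_a, density_b = f_b,
         overlap = sum(pmin(f_a, f_b)) * bin_width, bin_width = bin_width),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("APC distribution overlap\n")
  cat("  bins:", length(x$breaks) - 1, "of width", x$bin_width, "\n")
  cat("  overlap coefficient:", format(x$overlap, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.overlap_summary <- function(x, ...) {
  tibble(
    bin_lo = x$breaks[-length(x$breaks)],
    bin_hi = x$breaks[-1],
    density_a = x$density_a,
    density_b = x$density_b
  )
}

#' @export
glance.overlap_summary <- function(x, ...) {
  tibble(overlap = x$overlap, bin_width = x$bin_width,
         n_bins = length(x$breaks) - 1)
}
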