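#' Bonferroni adjustment
#'
#' Family-wise error-rate control: `p_bonf = min(1, m * p)`. Very
#' conservative for large families, which is exactly why region-rich
#' morphometry studies need FDR-based alternatives; kept as the
#' reference correction.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Rejection level for the flags.
#' @return Tibble `p`, `p_bonf`, `reject`.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  check_pvalues(p)
  p_bonf <- pmin(1, length(p) * p)
  tibble(p = p, p_bonf = p_bonf, reject = p_bonf < alpha)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts the p-values ascending, computes `p_(i) * m / i`, enforces
#' monotonicity by a cumulative minimum from the largest rank down,
#' caps at 1, and restores the original order. Ties receive identical
#' adjusted values. Rejecting rows with adjusted p below `alpha`
#' bounds the false discovery rate by `alpha` for independent tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (length >= 1).
#' @return Numeric vector of BH-adjusted p-values, `>= p` elementwise.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  check_pvalues(p)
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, p[ord] * m / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Estimate the proportion of true null hypotheses
#'
#' Storey-Tibshirani estimator of `pi0`, the fraction of tests whose
#' null hypothesis is true. For each `lambda` on the grid the raw
#' estimate `pi0(lambda) = #{p > lambda} / (m * (1 - lambda))` counts
#' how uniform the p-value tail looks beyond `lambda`; a cubic
#' smoothing spline (default 3 effective degrees of freedom) is fitted
#' to `pi0(lambda)` versus `lambda` and evaluated at the largest grid
#' point, where the alternative hypotheses contribute least. The
#' smoothed value is clamped into `(1/m, 1]`: estimates above 1 carry
#' no meaning (there cannot be more nulls than tests) and a floor of
#' `1/m` keeps downstream q-values positive.
#'
#' With fewer than 20 p-values, or when all p-values are identical,
#' the estimator is unreliable and falls back to `pi0 = 1` (the
#' Benjamini-Hochberg-equivalent choice) with a warning.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Strictly increasing grid in `[0, 0.95]`; default
#'   `seq(0.05, 0.90, by = 0.05)`.
#' @param df Effective degrees of freedom of the smoothing spline.
#' @return Object of class `pi0_estimate`: list with `lambda`,
#'   `raw_pi0`, `smoothed_pi0`, `final_pi0`, `clamped`, `m`.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.90, by = 0.05), df = 3) {
  check_pvalues(p)
  m <- length(p)
  if (is.unsorted(lambda, strictly = TRUE) ||
      any(lambda < 0) || any(lambda > 0.95)) {
    abort("`lambda` must be strictly increasing within [0, 0.95].")
  }
  raw <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))

  fallback <- function(msg) {
    warn(paste0(msg, " Falling back to pi0 = 1."))
    structure(list(lambda = lambda, raw_pi0 = raw, smoothed_pi0 = NA_real_,
                   final_pi0 = 1, clamped = FALSE, m = m),
              class = "pi0_estimate")
  }
  if (m < 20) return(fallback("Fewer than 20 p-values."))
  if (length(unique(p)) == 1) return(fallback("All p-values identical."))

  fit <- smooth.spline(lambda, raw, df = df)
  smoothed <- predict(fit, x = max(lambda))$y
  floor_pi0 <- 1 / m
  final <- min(max(smoothed, floor_pi0), 1)
  structure(
    list(lambda = lambda, raw_pi0 = raw, smoothed_pi0 = smoothed,
         final_pi0 = final, clamped = !identical(final, smoothed), m = m),
    class = "pi0_estimate"
  )
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat("pi0 estimate over", x$m, "tests\n")
  cat("  smoothed pi0(lambda_max):", format(x$smoothed_pi0, digits = 4),
      if (isTRUE(x$clamped)) "(clamped)" else "", "\n")
  cat("  final pi0:", format(x$final_pi0, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.pi0_estimate <- function(x, ...) {
  tibble(lambda = x$lambda, raw_pi0 = x$raw_pi0)
}

#' @export
glance.pi0_estimate <- function(x, ...) {
  tibble(m = x$m, smoothed_pi0 = x$smoothed_pi0,
         final_pi0 = x$final_pi0, clamped = x$clamped)
}

#' Storey q-values from p-values and a pi0 estimate
#'
#' `q_i = min over ranks j with p_j >= p_i of (pi0 * m * p_j / j)`,
#' capped at 1 -- equivalently `pi0` times the Benjamini-Hochberg
#' adjusted p-value. With `pi0 = 1` the q-values coincide with BH;
#' any `pi0 < 1` scales every adjusted value down by the same factor,
#' which is where the extra power of the Storey-Tibshirani correction
#' comes from.
#'
#' @inheritParams bh_adjust
#' @param pi0 Proportion of true nulls in `(0, 1]`, typically
#'   `estimate_pi0(p)$final_pi0`.
#' @return Numeric vector of q-values.
#' @export
qvalues <- function(p, pi0) {
  if (length(pi0) != 1 || is.na(pi0) || pi0 <= 0 || pi0 > 1) {
    abort("`pi0` must be a single value in (0, 1].")
  }
  pmin(1, pi0 * bh_adjust(p))
}

#' Applicability diagnostics for the Storey-Tibshirani correction
#'
#' The q-value machinery gains power over Benjamini-Hochberg only when
#' (1) the family is large, (2) p-values are approximately uniform
#' near 1 (so the tail identifies the nulls), and (3) the p-value
#' density peaks near 0 (so there are signals to find). This turns the
#' three conditions into executable checks:
#' \itemize{
#'   \item `cond_large_m`: `m >= 100`.
#'   \item `cond_uniform_tail`: the slope of the 10-bin histogram
#'     counts over `p` in `[0.5, 1]` is not significantly positive
#'     (one-sided test at 0.05). A rising tail means the p-values
#'     pile up near 1 faster than uniform, which biases `pi0` upward.
#'   \item `cond_peak_near_zero`: the count in `[0, 0.05]` exceeds the
#'     uniform expectation `m / 20` by a significant margin (one-sided
#'     binomial test at 0.05); a bare excess over the expectation would
#'     flip a fair coin on null data.
#' }
#' The verdict is the conjunction; when it is false, BH is the
#' recommended correction and q-values should be read with caution.
#'
#' @inheritParams bh_adjust
#' @return Object of class `conditions_report`: list with `m`, the
#'   three flags with their statistics, and `verdict`.
#' @export
storey_conditions <- function(p) {
  check_pvalues(p)
  m <- length(p)
  cond_large_m <- m >= 100

  tail_p <- p[p >= 0.5]
  bins <- seq(0.5, 1, length.out = 11)
  counts <- graphics::hist(tail_p, breaks = bins, plot = FALSE)$counts
  centers <- (bins[-1] + bins[-11]) / 2
  if (sum(counts) > 0 && sd(counts) > 0) {
    fit <- summary(lm(counts ~ centers))$coefficients
    slope <- fit["centers", "Estimate"]
    p_slope <- pt(fit["centers", "t value"], df = 8, lower.tail = FALSE)
  } else {
    slope <- 0
    p_slope <- 1
  }
  cond_uniform_tail <- !(p_slope < 0.05)

  peak_count <- sum(p <= 0.05)
  p_peak <- stats::pbinom(peak_count - 1, m, 0.05, lower.tail = FALSE)
  cond_peak_near_zero <- peak_count > m / 20 && p_peak < 0.05

  structure(
    list(m = m, cond_large_m = cond_large_m,
         tail_slope = slope, tail_slope_p = p_slope,
         cond_uniform_tail = cond_uniform_tail,
         peak_count = peak_count, peak_expected = m / 20,
         cond_peak_near_zero = cond_peak_near_zero,
         verdict = cond_large_m && cond_uniform_tail && cond_peak_near_zero),
    class = "conditions_report"
  )
}

#' @export
print.conditions_report <- function(x, ...) {
  yn <- function(b) if (b) "yes" else "no"
  cat("Storey-Tibshirani applicability (m =", x$m, ")\n")
  cat("  large family:        ", yn(x$cond_large_m), "\n")
  cat("  uniform tail:        ", yn(x$cond_uniform_tail),
      sprintf(" (slope %.1f, one-sided p %.3f)", x$tail_slope,
              x$tail_slope_p), "\n")
  cat("  peak near zero:      ", yn(x$cond_peak_near_zero),
      sprintf(" (%d observed vs %.1f expected in [0, 0.05])",
              x$peak_count, x$peak_expected), "\n")
  cat("  verdict:             ",
      if (x$verdict) "Storey q-values recommended"
      else "Benjamini-Hochberg recommended", "\n")
  invisible(x)
}

#' @export
glance.conditions_report <- function(x, ...) {
  tibble(m = x$m, cond_large_m = x$cond_large_m,
         cond_uniform_tail = x$cond_uniform_tail,
         cond_peak_near_zero = x$cond_peak_near_zero,
         verdict = x$verdict)
}

#' Multiplicity correction of a comparison table
#'
#' Partitions the comparison rows into correction families, and within
#' each family computes Bonferroni-adjusted p, BH-adjusted p, the
#' family's `pi0` estimate, Storey q-values and the applicability
#' diagnostics. Family scoping matters: adjusted values are only
#' comparable within the family they were corrected in.
#'
#' @param comparison Tibble from [compare_all()] (needs `roi_id`,
#'   `measure`, `stream`, `p`).
#' @param family_mode `"per-measure"` (default): one family per
#'   stream x measure; `"reproduce"`: one family for the whole
#'   volumetric stream and one joint family across all surface
#'   measures (the scoping that yields identical adjusted values for
#'   identical raw p across surface measures); `"global"`: a single
#'   family. Alternatively supply a `family` column on `comparison`
#'   beforehand and use `family_mode = "column"`.
#' @param alpha FDR level for the significance flags (default 0.05).
#' @param lambda,df Passed to [estimate_pi0()].
#' @return Object of class `mtc_result`: list with
#'   \describe{
#'     \item{table}{Tibble `roi_id`, `measure`, `stream`, `family`,
#'       `p`, `p_bonf`, `p_adj_bh`, `q`, `sig_bh`, `sig_q`.}
#'     \item{families}{Named list per family: `pi0` (a
#'       `pi0_estimate`), `conditions` (a `conditions_report`), and
#'       `recommended` ("storey" or "bh").}
#'     \item{alpha}{The FDR level used.}
#'   }
#' @export
correct_mtc <- function(comparison,
                        family_mode = c("per-measure", "reproduce",
                                        "global", "column"),
                        alpha = 0.05,
                        lambda = seq(0.05, 0.90, by = 0.05), df = 3) {
  family_mode <- match.arg(family_mode)
  tbl <- as_tibble(comparison)
  if (nrow(tbl) < 1) abort("`comparison` must contain at least one row.")
  fam <- switch(
    family_mode,
    "per-measure" = paste(tbl$stream, tbl$measure, sep = ":"),
    "reproduce" = ifelse(tbl$stream == "vbm", "vbm", "sbm"),
    "global" = "all",
    "column" = {
      if (!"family" %in% names(tbl)) {
        abort("`family_mode = \"column\"` needs a `family` column.")
      }
      as.character(tbl$family)
    }
  )
  tbl$family <- fam

  families <- list()
  pieces <- split(tbl, tbl$family)
  out <- lapply(names(pieces), function(f) {
    fam_tbl <- pieces[[f]]
    p <- fam_tbl$p
    pi0_est <- if (length(p) >= 20) estimate_pi0(p, lambda = lambda, df = df)
      else suppressWarnings(estimate_pi0(p, lambda = lambda, df = df))
    cond <- storey_conditions(p)
    families[[f]] <<- list(
      pi0 = pi0_est, conditions = cond,
      recommended = if (cond$verdict) "storey" else "bh"
    )
    fam_tbl |>
      mutate(
        p_bonf = pmin(1, length(p) * .data$p),
        p_adj_bh = bh_adjust(.data$p),
        q = qvalues(.data$p, pi0_est$final_pi0),
        sig_bh = .data$p_adj_bh < alpha,
        sig_q = .data$q < alpha
      )
  })
  table <- bind_rows(out) |>
    arrange(.data$family, .data$p) |>
    select(any_of(c("roi_id", "measure", "stream", "family", "p", "p_bonf",
                    "p_adj_bh", "q", "sig_bh", "sig_q")))
  structure(list(table = table, families = families, alpha = alpha),
            class = "mtc_result")
}

#' @export
print.mtc_result <- function(x, ...) {
  cat("Multiplicity correction over", nrow(x$table), "tests in",
      length(x$families), "family(ies), FDR alpha =", x$alpha, "\n")
  for (f in names(x$families)) {
    fam <- x$families[[f]]
    rows <- x$table[x$table$family == f, ]
    cat(sprintf(
      "  %s: m = %d, pi0 = %.3f, sig_bh = %d, sig_q = %d (%s recommended)\n",
      f, fam$pi0$m, fam$pi0$final_pi0, sum(rows$sig_bh), sum(rows$sig_q),
      fam$recommended))
  }
  invisible(x)
}

#' @export
tidy.mtc_result <- function(x, ...) {
  x$table
}

#' @export
glance.mtc_result <- function(x, ...) {
  purrr::map_dfr(names(x$families), function(f) {
    fam <- x$families[[f]]
    rows <- x$table[x$table$family == f, ]
    tibble(family = f, m = fam$pi0$m, pi0 = fam$pi0$final_pi0,
           conditions_met = fam$conditions$verdict,
           recommended = fam$recommended,
           n_sig_bh = sum(rows$sig_bh), n_sig_q = sum(rows$sig_q))
  })
}

check_pvalues <- function(p) {
  if (length(p) == 0) abort("Need at least one p-value.")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  invisible(p)
}
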