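#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_hline geom_vline labs theme_minimal coord_flip
#'   scale_fill_manual position_identity
NULL

#' @export
ggplot2::autoplot

#' Plot the overlaid group histograms behind an overlap summary
#'
#' The classic two-group APC histogram: bars of both groups' densities
#' on the shared bin grid, semi-transparent so the overlapping mass is
#' visible. The more the two distributions separate, the lower the
#' overlap coefficient reported by [distribution_overlap()].
#'
#' @param object An `overlap_summary`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.overlap_summary <- function(object, ...) {
  d <- tidy(object) |>
    mutate(mid = (.data$bin_lo + .data$bin_hi) / 2) |>
    tidyr::pivot_longer(c("density_a", "density_b"),
                        names_to = "sample", values_to = "density") |>
    mutate(sample = ifelse(.data$sample == "density_a", "case", "control"))
  ggplot(d, aes(x = .data$mid, y = .data$density, fill = .data$sample)) +
    geom_col(position = position_identity(), alpha = 0.5,
             width = object$bin_width) +
    labs(x = "group-mean APC (%)", y = "density",
         title = sprintf("Distribution overlap = %.3f", object$overlap)) +
    theme_minimal()
}

#' Plot a pi0 estimation trace
#'
#' Raw `pi0(lambda)` across the tuning grid with the final (smoothed,
#' clamped) estimate as a horizontal line. A flat right end of the
#' trace is what makes the estimate trustworthy; a rising or erratic
#' tail suggests the uniform-tail assumption is violated.
#'
#' @param object A `pi0_estimate`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pi0_estimate <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$lambda, y = .data$raw_pi0)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    geom_hline(yintercept = object$final_pi0, linetype = "dashed") +
    labs(x = expression(lambda), y = expression(hat(pi)[0](lambda)),
         title = sprintf("Final pi0 = %.3f%s", object$final_pi0,
                         if (isTRUE(object$clamped)) " (clamped)" else "")) +
    theme_minimal()
}

#' Horizontal bar plot of the strongest group differences
#'
#' Mirrors the standard presentation of region-level longitudinal
#' findings: one bar per feature, length equal to the case-minus-
#' control difference in group-mean APC, most significant rows first.
#' Bars to the left are regions declining faster in the case group.
#'
#' @param comparison An `apc_comparison` from [compare_all()].
#' @param top Number of rows (by ascending p) to display.
#' @return A ggplot.
#' @export
plot_comparison <- function(comparison, top = 20) {
  d <- as_tibble(comparison) |>
    arrange(.data$p) |>
    head(top) |>
    mutate(
      feature = paste0(.data$roi_id, " (", .data$measure, ")"),
      diff = .data$mean_a - .data$mean_b
    )
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$feature, y = .data$diff, fill = .data$sig_unc)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    coord_flip() +
    labs(x = NULL, y = "difference in group-mean APC (case - control, %)",
         fill = "p < alpha") +
    theme_minimal()
}
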