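#' Subject-to-group homogeneity scores
#'
#' Second-stage quality assurance for a longitudinal morphometry study:
#' each subject's full feature profile (every ROI x measure x visit
#' value) is correlated against the mean profile of the other members
#' of their group. A subject whose anatomy was segmented consistently
#' scores near 1; a corrupted segmentation decorrelates from the group
#' template and scores low. The score is the Pearson correlation
#' between the subject's feature vector and the leave-one-out group
#' mean vector, so it lies in `[-1, 1]` and is invariant under any
#' affine rescaling common to all subjects.
#'
#' @param measurements Long measurement table (`subject_id`, `group`,
#'   `roi_id`, `measure`, `value`, optionally `visit_date` to separate
#'   visits). Every subject must carry the identical feature set.
#' @return Tibble `subject_id`, `group`, `score`.
#' @export
homogeneity_scores <- function(measurements) {
  measurements <- as_tibble(measurements)
  needed <- c("subject_id", "group", "roi_id", "measure", "value")
  missing_cols <- setdiff(needed, names(measurements))
  if (length(missing_cols) > 0) {
    abort(paste0("`measurements` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if ("visit_date" %in% names(measurements)) {
    # visits align by order within subject, not by calendar date
    measurements <- measurements |>
      group_by(.data$subject_id, .data$roi_id, .data$measure) |>
      arrange(.data$visit_date, .by_group = TRUE) |>
      mutate(visit_idx = row_number()) |>
      ungroup()
  }
  key_cols <- intersect(c("roi_id", "measure", "stream", "visit_idx"),
                        names(measurements))
  measurements$feature <- do.call(paste,
                                  c(measurements[key_cols], sep = "|"))
  wide <- measurements |>
    select("subject_id", "group", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")

  feat_mat <- as.matrix(select(wide, -"subject_id", -"group"))
  rownames(feat_mat) <- wide$subject_id
  if (anyNA(feat_mat)) {
    idx <- which(is.na(feat_mat), arr.ind = TRUE)[1, ]
    abort(paste0("Subject ", rownames(feat_mat)[idx[1]],
                 " is missing feature ", colnames(feat_mat)[idx[2]], "."))
  }
  grp_sizes <- table(wide$group)
  if (any(grp_sizes < 3)) {
    abort("Every group needs at least 3 subjects for homogeneity scoring.")
  }
  if (any(apply(feat_mat, 1, sd) == 0)) {
    flat <- rownames(feat_mat)[apply(feat_mat, 1, sd) == 0]
    abort(paste0("Zero-variance feature vector for subject(s): ",
                 paste(flat, collapse = ", "), "."))
  }

  score <- numeric(nrow(wide))
  for (g in unique(wide$group)) {
    rows <- which(wide$group == g)
    gm <- colMeans(feat_mat[rows, , drop = FALSE])
    n_g <- length(rows)
    for (i in rows) {
      loo_mean <- (gm * n_g - feat_mat[i, ]) / (n_g - 1)
      score[i] <- cor(feat_mat[i, ], loo_mean)
    }
  }
  tibble(subject_id = wide$subject_id, group = wide$group, score = score)
}

#' Flag low-homogeneity subjects
#'
#' Lower-tail rule: a subject is an outlier when its score falls below
#' `group mean - k * group SD`, with mean and SD computed over all
#' group members including the candidates themselves (single pass, no
#' iterative re-scoring). Only the lower tail is tested: an unusually
#' high homogeneity score is not a quality problem. With a zero group
#' SD (all scores equal) nothing is flagged.
#'
#' @param scores Tibble from [homogeneity_scores()] (`subject_id`,
#'   `group`, `score`).
#' @param k SD multiplier, strictly positive; 2 is the conventional
#'   screening threshold.
#' @return `scores` with columns `threshold` and `excluded` appended.
#' @export
flag_outliers <- function(scores, k = 2) {
  if (k <= 0) abort("`k` must be strictly positive.")
  scores <- as_tibble(scores)
  grp_sizes <- table(scores$group)
  if (any(grp_sizes < 3)) {
    abort("Every group needs at least 3 scores for outlier flagging.")
  }
  scores |>
    group_by(.data$group) |>
    mutate(threshold = mean(.data$score) - k * sd(.data$score),
           excluded = .data$score < .data$threshold) |>
    ungroup()
}

#' Run homogeneity quality assurance on a cohort
#'
#' Convenience wrapper: scores every subject with
#' [homogeneity_scores()], applies the `k`-SD lower-tail exclusion rule
#' with [flag_outliers()], and returns a classed report with per-group
#' summaries for [tidy()] / [glance()].
#'
#' @inheritParams homogeneity_scores
#' @inheritParams flag_outliers
#' @return Object of class `homogeneity_report`: tibble `subject_id`,
#'   `group`, `score`, `threshold`, `excluded`, with the SD multiplier
#'   in attribute `k`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_per_group = 5,
#'   roi_spec = tidyr::crossing(roi_id = c("L_Hippocampus", "R_Hippocampus"),
#'                              measure = "volume", stream = "vbm"),
#'   seed = 7
#' ))
#' qa_homogeneity(cohort$measurements)
#' @export
qa_homogeneity <- function(measurements, k = 2) {
  report <- flag_outliers(homogeneity_scores(measurements), k = k)
  n_exc <- sum(report$excluded)
  if (n_exc > 0) {
    exc <- filter(report, .data$excluded)
    inform(paste0("QA excluded ", n_exc, " subject(s): ",
                  paste0(exc$subject_id, " (", exc$group, ", score ",
                         sprintf("%.3f", exc$score), ")",
                         collapse = ", "), "."))
  }
  structure(report, class = c("homogeneity_report", class(report)), k = k)
}

#' @export
tidy.homogeneity_report <- function(x, ...) {
  as_tibble(unclass_report(x))
}

#' @export
glance.homogeneity_report <- function(x, ...) {
  as_tibble(unclass_report(x)) |>
    group_by(.data$group) |>
    summarise(n = n(), mean_score = mean(.data$score),
              sd_score = sd(.data$score), n_excluded = sum(.data$excluded),
              .groups = "drop") |>
    mutate(k = attr(x, "k"))
}

unclass_report <- function(x) {
  class(x) <- setdiff(class(x), "homogeneity_report")
  x
}
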