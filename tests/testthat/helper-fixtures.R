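# Small in-code fixtures shared across test files.

tiny_roi_spec <- function(rois = c("L_Hippocampus", "R_Hippocampus"),
                          measure = "volume", stream = "vbm") {
  tidyr::crossing(roi_id = rois, measure = measure, stream = stream)
}

# a flat rate map: same q in both groups unless case rates are supplied
flat_rate_map <- function(roi_spec, q = -0.02, groups = c("AD", "CN"),
                          q_case = NULL) {
  out <- tidyr::crossing(group = groups, roi_spec) |>
    dplyr::mutate(q_true = q) |>
    dplyr::select(group, roi_id, measure, q_true)
  if (!is.null(q_case)) {
    out$q_true[out$group == groups[1]] <- q_case
  }
  out
}

# deterministic-rate fixture: no between-subject progression spread
small_cohort_config <- function(n_per_group = 5, q = -0.02, q_case = NULL,
                                noise_sigma = 0, jitter = 0, seed = 1,
                                rois = c("L_Hippocampus", "R_Hippocampus"),
                                ...) {
  spec <- tiny_roi_spec(rois)
  cohort_config(
    n_per_group = n_per_group,
    roi_spec = spec,
    rate_map = flat_rate_map(spec, q = q, q_case = q_case),
    noise_sigma = noise_sigma,
    interval_jitter_days = jitter,
    subject_rate_sd = 0,
    seed = seed,
    ...
  )
}

# hand-built two-visit measurement table
paired_measurements <- function(x1, x2, delta_days = 365,
                                subject_id = sprintf("S%02d", seq_along(x1)),
                                group = "A", roi_id = "roi1",
                                measure = "volume", stream = "vbm") {
  base <- as.Date("2020-01-01")
  dplyr::bind_rows(
    tibble::tibble(subject_id = subject_id, group = group,
                   visit_date = base, roi_id = roi_id, measure = measure,
                   stream = stream, value = x1),
    tibble::tibble(subject_id = subject_id, group = group,
                   visit_date = base + delta_days, roi_id = roi_id,
                   measure = measure, stream = stream, value = x2)
  )
}

# brute-force BH step-up: find, for each p_i, the smallest alpha at which
# the classic step-up procedure rejects it
bh_brute_force <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    candidates <- vapply(seq_len(m), function(j) {
      # adjusted value implied by rejecting at rank j
      sorted <- sort(p)
      sorted[j] * m / j
    }, numeric(1))
    sorted <- sort(p)
    rank_i <- max(which(sorted <= p[i] + 1e-15))
    min(1, min(candidates[rank_i:m]))
  }, numeric(1))
}
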