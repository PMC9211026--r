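test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- small_cohort_config(noise_sigma = 0.03, jitter = 30, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$cognition, b$cognition)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(small_cohort_config(noise_sigma = 0.03,
                                            jitter = 30, seed = 43))
  expect_false(identical(a$measurements$value, c2$measurements$value))
})

test_that("all generated measurements are strictly positive", {
  cfg <- small_cohort_config(n_per_group = 10, q = -0.5,
                             noise_sigma = 0.5, jitter = 60, seed = 9)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$measurements$value > 0))
})

test_that("the generative model is the exponential model", {
  # no noise, no jitter, zero rate: follow-up equals baseline exactly
  cfg0 <- small_cohort_config(q = 0, noise_sigma = 0, jitter = 0, seed = 2)
  m0 <- generate_cohort(cfg0)$measurements
  both <- m0 |>
    dplyr::arrange(subject_id, roi_id, measure, visit_date) |>
    dplyr::group_by(subject_id, roi_id, measure) |>
    dplyr::summarise(x1 = value[1], x2 = value[2], .groups = "drop")
  expect_identical(both$x1, both$x2)

  # -5%/yr with a clean year: downstream APC is exactly -5
  cfg5 <- small_cohort_config(q = -0.05, noise_sigma = 0, jitter = 0,
                              seed = 2)
  tbl <- apc_table(generate_cohort(cfg5)$measurements)
  expect_equal(tbl$apc, rep(-5, nrow(tbl)), tolerance = 1e-10)
})

test_that("observed intervals stay within the configured jitter in whole days", {
  cfg <- small_cohort_config(n_per_group = 50, jitter = 45, seed = 31)
  subj <- generate_cohort(cfg)$truth$subjects
  expect_true(all(abs(subj$delta_days - 365) <= 45))
  expect_true(all(subj$delta_days == round(subj$delta_days)))
  expect_true(length(unique(subj$delta_days)) > 5)
})

test_that("invalid generative parameters are rejected by name", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  spec <- tiny_roi_spec()
  expect_error(
    cohort_config(roi_spec = spec,
                  rate_map = flat_rate_map(spec, q = -1.2)),
    "q_true")
  expect_error(
    cohort_config(roi_spec = spec, interval_jitter_days = 400),
    "interval_jitter_days")
  expect_error(cohort_config(roi_spec = spec, noise_sigma = -1),
               "noise_sigma")
  bad_baseline <- dplyr::mutate(default_baseline_map(spec), sdlog = -0.1)
  expect_error(cohort_config(roi_spec = spec, baseline_map = bad_baseline),
               "sdlog")
})

test_that("truth labels nulls exactly when group rates coincide", {
  spec <- tiny_roi_spec(c("L_Hippocampus", "L_ctx_001"))
  rates <- flat_rate_map(spec, q = -0.01)
  rates$q_true[rates$group == "AD" & rates$roi_id == "L_Hippocampus"] <- -0.04
  cohort <- generate_cohort(cohort_config(n_per_group = 3, roi_spec = spec,
                                          rate_map = rates, seed = 1))
  truth <- cohort$truth$features
  expect_false(truth$is_null[truth$roi_id == "L_Hippocampus"])
  expect_true(truth$is_null[truth$roi_id == "L_ctx_001"])
})

test_that("default cohort carries the documented study structure", {
  spec <- default_roi_spec()
  expect_equal(sum(spec$stream == "vbm"), 88)
  expect_equal(sum(spec$stream == "sbm"), 360 * 5)
  rm <- default_rate_map(spec)
  hip <- rm[rm$roi_id == "L_Hippocampus" & rm$measure == "volume", ]
  expect_equal(hip$q_true[hip$group == "AD"], -0.044)
  expect_equal(hip$q_true[hip$group == "CN"], -0.0032)
})

test_that("p-value mixture has uniform nulls and concentrated alternatives", {
  mix1 <- generate_pvalue_mixture(10000, pi0 = 1, seed = 4)
  expect_true(all(mix1$is_null))
  ks <- suppressWarnings(stats::ks.test(mix1$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  mix0 <- generate_pvalue_mixture(500, pi0 = 0, effect = 6, seed = 4)
  expect_true(all(!mix0$is_null))
  expect_lt(max(mix0$p), 0.5)

  mix <- generate_pvalue_mixture(1000, pi0 = 0.6, seed = 4)
  expect_equal(sum(mix$is_null), 600)

  expect_error(generate_pvalue_mixture(0, pi0 = 0.5), "at least 1")
  expect_error(generate_pvalue_mixture(10, pi0 = 1.2), "0, 1")
})

test_that("cognitive scores respect instrument ranges and couple to atrophy", {
  cfg <- cohort_config(n_per_group = 25,
                       roi_spec = tiny_roi_spec(),
                       rate_map = flat_rate_map(tiny_roi_spec(),
                                                q = -0.005,
                                                q_case = -0.05),
                       seed = 8)
  cog <- generate_cohort(cfg)$cognition
  mmse <- cog[cog$instrument == "MMSE", ]
  expect_true(all(mmse$score >= 0 & mmse$score <= 30))
  expect_true(all(cog$score >= 0))
  deltas <- score_change(cog)
  mean_delta <- tapply(deltas$delta,
                       list(deltas$group, deltas$instrument), mean)
  # faster atrophy in the case group: MMSE falls harder, CDR/FAQ rise harder
  expect_lt(mean_delta["AD", "MMSE"], mean_delta["CN", "MMSE"])
  expect_gt(mean_delta["AD", "CDR_GLOBAL"], mean_delta["CN", "CDR_GLOBAL"])
  expect_gt(mean_delta["AD", "FAQ_TOTAL"], mean_delta["CN", "FAQ_TOTAL"])
})
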