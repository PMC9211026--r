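# published group summaries (mean, SD per group, n = 25 each) whose
# pooled-test p-values are known to 4 decimals
published_rows <- tibble::tribble(
  ~label, ~mean_a, ~sd_a, ~mean_b, ~sd_b, ~p4,
  "R_Hippocampus volume",  -3.87, 3.94,  0.43, 3.94, 0.0003,
  "L_Amygdala volume",     -7.36, 6.13, -1.37, 6.61, 0.0017,
  "R_TGd volume",          -5.38, 3.95, -0.83, 3.46, 0.0001,
  "R_EC area",             -5.44, 5.93,  2.14, 6.70, 0.0001,
  "R_s6-8 thickness",      -2.86, 2.75,  0.05, 2.04, 0.0001,
  "R_TE2a volume",         -2.78, 2.49,  0.97, 4.35, 0.0005,
  "L_TF volume",           -3.82, 3.83,  0.30, 3.27, 0.0002
)

test_that("pooled t-test from summaries reproduces published 4-decimal p-values", {
  res <- ttest_from_summary(published_rows$mean_a, published_rows$sd_a, 25,
                            published_rows$mean_b, published_rows$sd_b, 25)
  expect_equal(res$df, rep(48, nrow(published_rows)))
  expect_equal(round(res$p, 4), published_rows$p4)
})

test_that("degenerate and identical summaries are handled as defined", {
  same <- ttest_from_summary(1.5, 2, 10, 1.5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  both_zero <- ttest_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(both_zero$p, 1)
  expect_warning(degen <- ttest_from_values(c(0, 0), c(1, 1)),
                 "Zero within-group variance")
  expect_equal(degen$p, 0)
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 5), "at least 2")
})

test_that("pooled and Welch agree on t for equal n and equal SDs", {
  pooled <- ttest_from_summary(-3, 2.5, 20, -1, 2.5, 20)
  welch <- ttest_from_summary(-3, 2.5, 20, -1, 2.5, 20, variant = "welch")
  expect_equal(pooled$t, welch$t)
  expect_equal(pooled$df, 38)
  expect_equal(welch$df, 38)  # Satterthwaite collapses to pooled here
})

test_that("raw-value path matches summaries and the stats reference", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), mean = runif(1, -3, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -3, 1), sd = runif(1, .5, 3))
    for (variant in c("pooled", "welch")) {
      mine <- ttest_from_values(a, b, variant = variant)
      via_summary <- ttest_from_summary(mean(a), sd(a), length(a),
                                        mean(b), sd(b), length(b),
                                        variant = variant)
      expect_equal(mine, via_summary, tolerance = 1e-12)
      ref <- stats::t.test(a, b, var.equal = variant == "pooled")
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("t changes sign but p is invariant under label swap and shift", {
  set.seed(2)
  a <- rnorm(12, -2, 3)
  b <- rnorm(15, 0, 2)
  fwd <- ttest_from_values(a, b)
  rev <- ttest_from_values(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  shifted <- ttest_from_values(a + 11.3, b + 11.3)
  expect_equal(fwd$t, shifted$t, tolerance = 1e-10)
  expect_equal(fwd$p, shifted$p, tolerance = 1e-10)
})

test_that("compare_all matches the single-comparison path and orders by p", {
  cfg <- small_cohort_config(n_per_group = 8, q = -0.005, q_case = -0.05,
                             noise_sigma = 0.03, jitter = 30, seed = 12,
                             rois = c("L_Hippocampus", "L_ctx_001"))
  tbl <- apc_table(generate_cohort(cfg)$measurements)
  cmp <- compare_all(tbl, case = "AD", control = "CN")
  expect_true(!is.unsorted(cmp$p))
  one <- tbl[tbl$roi_id == "L_Hippocampus", ]
  direct <- ttest_from_values(one$apc[one$group == "AD"],
                              one$apc[one$group == "CN"])
  row <- cmp[cmp$roi_id == "L_Hippocampus", ]
  expect_equal(row$t, direct$t)
  expect_equal(row$p, direct$p)
  expect_error(compare_all(tbl, case = "AD", control = "XX"), "present")
})

test_that("power grows with the group rate separation", {
  power_at <- function(q_case, seed) {
    hits <- 0
    for (r in 1:40) {
      cfg <- small_cohort_config(n_per_group = 10, q = -0.005,
                                 q_case = q_case, noise_sigma = 0.03,
                                 jitter = 30, seed = seed + r,
                                 rois = "L_Hippocampus")
      tbl <- apc_table(generate_cohort(cfg)$measurements)
      hits <- hits + (compare_all(tbl, case = "AD")$p[1] < 0.05)
    }
    hits / 40
  }
  weak <- power_at(-0.015, seed = 100)
  strong <- power_at(-0.06, seed = 200)
  # 3 SEs of a 40-replicate proportion is at most 0.24
  expect_gt(strong, weak - 0.24)
  expect_gt(strong, 0.9)
})

test_that("distribution overlap has the right extremes and Gaussian value", {
  x <- rnorm(100)
  expect_equal(distribution_overlap(x, x)$overlap, 1, tolerance = 1e-10)
  expect_equal(distribution_overlap(c(0, 1, 2), c(10, 11, 12))$overlap, 0)
  set.seed(5)
  a <- rnorm(10000)
  b <- rnorm(10000, mean = 2)
  ov <- distribution_overlap(a, b, bin_width = 0.25)
  expect_equal(ov$overlap, 2 * pnorm(-1), tolerance = 0.02)
  expect_error(distribution_overlap(numeric(0), 1:3), "at least 2")
  s <- glance(ov)
  expect_equal(s$overlap, ov$overlap)
})
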