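test_that("Bonferroni multiplies by the family size and caps at 1", {
  expect_equal(bonferroni(0.01)$p_bonf, 0.01)
  expect_equal(bonferroni(c(0.01, 0.5))$p_bonf, c(0.02, 1))
  expect_error(bonferroni(numeric(0)), "at least one")
  expect_error(bonferroni(c(0.1, 1.2)), "0, 1")
})

test_that("Bonferroni controls the family-wise error on uniform nulls", {
  set.seed(3)
  fwer_hits <- vapply(1:400, function(i) {
    any(bonferroni(runif(1000))$reject)
  }, logical(1))
  rate <- mean(fwer_hits)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("BH step-up matches hand-worked and brute-force oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)

  set.seed(14)
  p6 <- round(runif(6), 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (i in seq_len(nrow(perms))) {
    pp <- p6[perms[i, ]]
    expect_equal(bh_adjust(pp), bh_brute_force(pp), tolerance = 1e-12)
  }

  # independent library implementation as a second oracle
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-14)
  }
})

test_that("BH adjustment sits between the raw p and Bonferroni", {
  set.seed(8)
  for (i in 1:10) {
    p <- runif(30)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-15))
  }
})

test_that("pi0 estimation recovers the null fraction", {
  set.seed(100)
  est1 <- estimate_pi0(runif(10000))
  expect_lt(abs(est1$final_pi0 - 1), 0.05)

  mix <- generate_pvalue_mixture(5000, pi0 = 0.6, effect = 3, seed = 2024)
  est06 <- estimate_pi0(mix$p)
  expect_lt(abs(est06$final_pi0 - 0.6), 0.07)
  expect_true(est06$final_pi0 > 0 && est06$final_pi0 <= 1)
})

test_that("pi0 estimation clamps and falls back on degenerate input", {
  expect_warning(est <- estimate_pi0(rep(1, 50)), "identical")
  expect_equal(est$final_pi0, 1)
  expect_warning(est_small <- estimate_pi0(runif(10)), "Fewer than 20")
  expect_equal(est_small$final_pi0, 1)
  expect_error(estimate_pi0(runif(100), lambda = c(0.5, 0.4)),
               "strictly increasing")
  # all p very large: raw pi0 > 1, clamped into (0, 1]
  set.seed(4)
  big <- estimate_pi0(runif(1000, 0.6, 1))
  expect_lte(big$final_pi0, 1)
  expect_true(big$clamped)
})

test_that("q-values are pi0 times the BH adjustment, exactly", {
  set.seed(21)
  p <- runif(200)
  expect_equal(qvalues(p, 1), bh_adjust(p))
  for (pi0 in c(0.25, 0.625, 0.9)) {
    q <- qvalues(p, pi0)
    bh <- bh_adjust(p)
    uncapped <- pi0 * bh < 1
    expect_equal(q[uncapped] / bh[uncapped],
                 rep(pi0, sum(uncapped)), tolerance = 1e-12)
  }
  ps <- sort(p)
  expect_true(!is.unsorted(qvalues(ps, 0.7)))
  expect_error(qvalues(p, 0), "0, 1")
  expect_error(qvalues(p, 1.3), "0, 1")
})

test_that("applicability diagnostics separate null from mixed families", {
  set.seed(2)
  unif <- storey_conditions(runif(5000))
  expect_true(unif$cond_large_m)
  expect_true(unif$cond_uniform_tail)
  expect_false(unif$cond_peak_near_zero)
  expect_false(unif$verdict)

  mix <- generate_pvalue_mixture(1800, pi0 = 0.6, effect = 3, seed = 77)
  mixed <- storey_conditions(mix$p)
  expect_true(mixed$verdict)

  tiny <- storey_conditions(rep(0.001, 10))
  expect_false(tiny$cond_large_m)
  expect_false(tiny$verdict)
})

test_that("correct_mtc scopes families and flags at the FDR level", {
  mix <- generate_pvalue_mixture(300, pi0 = 0.7, effect = 3.5, seed = 5)
  cmp <- tibble::tibble(
    roi_id = sprintf("roi%03d", seq_len(300)),
    measure = rep(c("volume", "area", "thickness"), each = 100),
    stream = "sbm", p = mix$p
  )
  per_measure <- correct_mtc(cmp, family_mode = "per-measure")
  expect_equal(length(per_measure$families), 3)
  joint <- correct_mtc(cmp, family_mode = "reproduce")
  expect_equal(length(joint$families), 1)
  tbl <- tidy(joint)
  expect_true(all(tbl$p <= tbl$p_adj_bh + 1e-15))
  expect_true(all(tbl$p_adj_bh <= tbl$p_bonf + 1e-15))
  pi0 <- joint$families$sbm$pi0$final_pi0
  expect_true(all(abs(tbl$q - pmin(1, pi0 * tbl$p_adj_bh)) < 1e-12))
  # Storey rejections contain the BH rejections whenever pi0 <= 1
  expect_true(all(tbl$sig_q >= tbl$sig_bh))
  g <- glance(joint)
  expect_equal(g$n_sig_q, sum(tbl$sig_q))
})

test_that("a family of one test falls back to pi0 = 1", {
  cmp <- tibble::tibble(roi_id = "solo", measure = "volume",
                        stream = "vbm", p = 0.03)
  res <- suppressWarnings(correct_mtc(cmp))
  expect_equal(tidy(res)$q, 0.03)
  expect_equal(res$families[[1]]$pi0$final_pi0, 1)
})

test_that("uniform-null families yield (near) zero Storey discoveries", {
  set.seed(123)
  n_sig <- vapply(1:20, function(i) {
    cmp <- tibble::tibble(roi_id = sprintf("r%03d", 1:500),
                          measure = "volume", stream = "vbm",
                          p = runif(500))
    sum(tidy(suppressWarnings(correct_mtc(cmp)))$sig_q)
  }, numeric(1))
  expect_lt(mean(n_sig > 0), 0.25)
})

test_that("realized FDR of Storey calls stays at the nominal level", {
  set.seed(31)
  for (pi0 in c(0.5, 0.8)) {
    fdrs <- vapply(1:60, function(i) {
      mix <- generate_pvalue_mixture(500, pi0 = pi0, effect = 3,
                                     seed = 5000 + i + round(1000 * pi0))
      est <- estimate_pi0(mix$p)
      sig <- qvalues(mix$p, est$final_pi0) < 0.05
      if (!any(sig)) return(0)
      sum(sig & mix$is_null) / sum(sig)
    }, numeric(1))
    se <- stats::sd(fdrs) / sqrt(length(fdrs))
    expect_lte(mean(fdrs), 0.05 + 3 * se)
  }
})
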