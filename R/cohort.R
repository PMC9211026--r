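#' Configuration for a synthetic two-group longitudinal morphometry cohort
#'
#' Bundles the generative parameters for [generate_cohort()]. Defaults
#' emulate a small Alzheimer's-disease-versus-control study: 25 subjects
#' per group, an 88-region volumetric (VBM) stream plus a 360-region
#' surface (SBM) stream with five measures per region, follow-up about a
#' year after baseline with the return date jittered by up to
#' `interval_jitter_days`, multiplicative log-normal measurement noise,
#' and cognitive scores whose one-year change is coupled to each
#' subject's mean true atrophy rate.
#'
#' @param n_per_group Subjects per group (>= 2). Default 25.
#' @param groups Length-2 character vector, case group first.
#' @param roi_spec Tibble with columns `roi_id`, `measure`, `stream`
#'   listing the features to simulate. Default [default_roi_spec()].
#' @param rate_map Tibble with columns `group`, `roi_id`, `measure`,
#'   `q_true`: the true annual rate (fraction per year, > -1) for every
#'   group x feature. Default [default_rate_map()] on `roi_spec`.
#' @param baseline_map Tibble with columns `roi_id`, `measure`,
#'   `meanlog`, `sdlog`: log-normal baseline parameters per feature.
#'   Default [default_baseline_map()] on `roi_spec` (volumes in the
#'   thousands, thicknesses near 2.5, all strictly positive).
#' @param interval_mean_days Nominal follow-up interval (days).
#' @param interval_jitter_days Maximum absolute deviation of the
#'   observed interval from nominal, in whole days; must be smaller
#'   than `interval_mean_days`.
#' @param noise_sigma SD of the multiplicative log-scale measurement
#'   noise applied to the follow-up value. Default 0.03, which yields
#'   APC standard deviations of about 3 percentage points, the order
#'   seen in region-level morphometry.
#' @param noise_on_baseline If `TRUE`, independent noise of the same SD
#'   is also applied to the baseline value (default `FALSE`: noise on
#'   the follow-up only, the simplest model consistent with APC's ratio
#'   form).
#' @param subject_rate_sd SD (fraction/yr) of a per-subject shift added
#'   to every feature's annual rate: subjects progress at different
#'   speeds, and this shared heterogeneity is what couples regional
#'   atrophy to cognitive decline within a group. Set to 0 for a
#'   deterministic-rate cohort.
#' @param cognition_coupling Named numeric vector, per instrument: the
#'   slope linking a subject's mean true annual rate (fraction/yr) to
#'   the one-year change in that instrument's score.
#' @param cognition_intercept Named numeric vector, per instrument:
#'   score change for a subject with mean rate zero.
#' @param cognition_noise_sd Named numeric vector, per instrument: SD
#'   of the Gaussian noise on the score change.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   the cohort exactly.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 25,
                          groups = c("AD", "CN"),
                          roi_spec = default_roi_spec(),
                          rate_map = default_rate_map(roi_spec, groups),
                          baseline_map = default_baseline_map(roi_spec),
                          interval_mean_days = 365,
                          interval_jitter_days = 45,
                          noise_sigma = 0.03,
                          noise_on_baseline = FALSE,
                          subject_rate_sd = 0.02,
                          cognition_coupling = c(
                            MMSE = 120, CDR_GLOBAL = -42,
                            FAQ_TOTAL = -240, NPI_TOTAL = -200),
                          cognition_intercept = c(
                            MMSE = -0.2, CDR_GLOBAL = -0.2,
                            FAQ_TOTAL = -0.5, NPI_TOTAL = 0.7),
                          cognition_noise_sd = c(
                            MMSE = 2, CDR_GLOBAL = 0.3,
                            FAQ_TOTAL = 3, NPI_TOTAL = 5),
                          seed = 1L) {
  if (n_per_group < 2) abort("`n_per_group` must be at least 2.")
  if (length(groups) != 2 || anyDuplicated(groups)) {
    abort("`groups` must be two distinct labels.")
  }
  roi_spec <- as_tibble(roi_spec)
  rate_map <- as_tibble(rate_map)
  baseline_map <- as_tibble(baseline_map)
  if (any(rate_map$q_true <= -1)) {
    abort("`rate_map$q_true` must be greater than -1 everywhere.")
  }
  if (any(baseline_map$sdlog < 0)) {
    abort("`baseline_map$sdlog` must be non-negative.")
  }
  if (interval_jitter_days < 0 ||
      interval_jitter_days >= interval_mean_days) {
    abort("`interval_jitter_days` must be in [0, interval_mean_days).")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be non-negative.")
  if (subject_rate_sd < 0) abort("`subject_rate_sd` must be non-negative.")
  # every feature needs a rate for both groups and baseline parameters
  need <- tidyr::crossing(group = groups, roi_spec)
  got <- left_join(need, rate_map, by = c("group", "roi_id", "measure"))
  if (any(is.na(got$q_true))) {
    miss <- got[is.na(got$q_true), ]
    abort(paste0("`rate_map` is missing ", nrow(miss), " group x feature ",
                 "entries, e.g. ", miss$group[1], "/", miss$roi_id[1],
                 "/", miss$measure[1], "."))
  }
  got_b <- left_join(roi_spec, baseline_map, by = c("roi_id", "measure"))
  if (any(is.na(got_b$meanlog))) {
    abort("`baseline_map` does not cover every feature in `roi_spec`.")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), groups = groups,
      roi_spec = roi_spec, rate_map = rate_map, baseline_map = baseline_map,
      interval_mean_days = interval_mean_days,
      interval_jitter_days = as.integer(interval_jitter_days),
      noise_sigma = noise_sigma, noise_on_baseline = noise_on_baseline,
      subject_rate_sd = subject_rate_sd,
      cognition_coupling = cognition_coupling,
      cognition_intercept = cognition_intercept,
      cognition_noise_sd = cognition_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default feature panel: 88 volumetric regions plus 360 surface regions
#'
#' The volumetric (VBM) stream carries 88 volume features: 19
#' subcortical regions in the Harvard-Oxford tradition (hippocampus,
#' amygdala, thalamus, ...), 64 hippocampal-subfield/amygdala-nucleus
#' style subdivisions and 5 brainstem subregions. The surface (SBM)
#' stream carries the 360 cortical parcels of an HCP-MMP-style
#' parcellation, each with five measures: volume, area, thickness,
#' gyrification and depth. Region names not taken from a published
#' atlas table are synthetic placeholders (`L_ctx_###`, `subfield_##`).
#'
#' @return Tibble with columns `roi_id`, `measure`, `stream`
#'   (88 + 360 x 5 = 1888 rows).
#' @export
default_roi_spec <- function() {
  subcortical <- c(
    "Brain_Stem",
    paste0(rep(c("L_", "R_"), each = 9),
           rep(c("Hippocampus", "Amygdala", "Thalamus", "Caudate",
                 "Putamen", "Pallidum", "Accumbens", "VentralDC",
                 "Cerebellum"), 2))
  )
  subfields <- sprintf("%s_subfield_%02d", rep(c("L", "R"), each = 32), 1:32)
  brainstem <- sprintf("brainstem_%d", 1:5)
  vbm <- tibble(roi_id = c(subcortical, subfields, brainstem),
                measure = "volume", stream = "vbm")

  named_sbm <- c("L_VVC", "L_PH", "R_TGd", "R_PFm", "L_TGd", "L_PF",
                 "L_TF", "L_TE1p", "L_A4", "L_FST", "L_TE1a", "L_PeEc",
                 "R_TE2a", "R_EC", "L_FFC", "L_9a", "R_33pr", "L_IFJa",
                 "R_s6-8", "L_TE2p", "L_EC", "R_TF", "R_PH", "R_VVC")
  n_fill <- 360 - length(named_sbm)
  filler <- sprintf("%s_ctx_%03d", rep(c("L", "R"), length.out = n_fill),
                    seq_len(n_fill))
  sbm <- tidyr::crossing(
    roi_id = c(named_sbm, filler),
    measure = c("volume", "area", "thickness", "gyrification", "depth")
  ) |>
    mutate(stream = "sbm")
  bind_rows(vbm, sbm)
}

#' Default true annual rates for a two-group atrophy cohort
#'
#' The case group receives accelerated decline in a medial-temporal /
#' temporo-parietal set of regions (hippocampus-like volumetric rates
#' near -4.4%/yr against -0.3%/yr in controls, cortical volume, area
#' and thickness effects of -2 to -9%/yr against roughly flat
#' controls); every other feature is null -- both groups share the same
#' mild age-related rate, spread smoothly across regions between
#' -2%/yr and +0.5%/yr (gyrification and depth closer to zero). The
#' spread keeps group-mean APC histograms realistically wide without
#' introducing spurious group differences.
#'
#' @param roi_spec Feature panel as in [default_roi_spec()].
#' @param groups Length-2 character vector, case group first.
#' @return Tibble `group`, `roi_id`, `measure`, `q_true`.
#' @export
default_rate_map <- function(roi_spec, groups = c("AD", "CN")) {
  affected <- tibble::tribble(
    ~roi_id, ~measure, ~q_case, ~q_ctrl,
    "L_Hippocampus", "volume", -0.0440, -0.0032,
    "R_Hippocampus", "volume", -0.0387,  0.0043,
    "L_Amygdala",    "volume", -0.0736, -0.0137,
    "L_VVC",  "volume", -0.0450,  0.0202,
    "L_PH",   "volume", -0.0298,  0.0176,
    "R_TGd",  "volume", -0.0538, -0.0083,
    "R_PFm",  "volume", -0.0199, -0.0005,
    "L_TGd",  "volume", -0.0590,  0.0012,
    "L_PF",   "volume", -0.0293, -0.0049,
    "L_TF",   "volume", -0.0382,  0.0030,
    "L_TE1p", "volume", -0.0373, -0.0013,
    "L_A4",   "volume", -0.0390, -0.0083,
    "L_FST",  "volume", -0.0244,  0.0155,
    "L_TE1a", "volume", -0.0491, -0.0020,
    "L_PeEc", "volume", -0.0650, -0.0125,
    "R_TE2a", "volume", -0.0278,  0.0097,
    "R_EC",   "volume", -0.0884,  0.0042,
    "L_FFC",  "volume", -0.0189,  0.0111,
    "R_EC",   "area",   -0.0544,  0.0214,
    "L_9a",   "area",   -0.0210,  0.0075,
    "L_PH",   "area",   -0.0210,  0.0002,
    "R_33pr", "area",   -0.0272, -0.0006,
    "L_IFJa", "area",   -0.0177,  0.0028,
    "R_s6-8", "thickness", -0.0286,  0.0005,
    "L_TE2p", "thickness", -0.0206,  0.0111
  )
  null_rate <- function(roi_id, measure) {
    # smooth deterministic spread per feature, identical in both groups
    u <- feature_u(roi_id, measure)
    amp <- ifelse(measure %in% c("gyrification", "depth"), 0.006, 0.025)
    lo <- ifelse(measure %in% c("gyrification", "depth"), -0.003, -0.02)
    lo + amp * u
  }

  base <- roi_spec |>
    mutate(q_null = null_rate(.data$roi_id, .data$measure))
  out <- tidyr::crossing(group = groups, base) |>
    left_join(
      tibble(group = rep(groups, each = nrow(affected)),
             roi_id = rep(affected$roi_id, 2),
             measure = rep(affected$measure, 2),
             q_eff = c(affected$q_case, affected$q_ctrl)),
      by = c("group", "roi_id", "measure")
    ) |>
    mutate(q_true = ifelse(is.na(.data$q_eff), .data$q_null, .data$q_eff)) |>
    select("group", "roi_id", "measure", "q_true")
  out
}

#' Default log-normal baseline parameters per feature
#'
#' Baselines are log-normal (strictly positive, right-skewed like real
#' region volumes), with location set by the measure's natural scale:
#' volumes around 3000 mm^3 (subcortical) or 1500 mm^3 (cortical
#' parcels), areas around 500 mm^2, thickness around 2.5 mm,
#' gyrification around 25 and sulcal depth around 10, plus a fixed
#' per-region offset spanning about a factor of e in either direction
#' -- real regions differ in characteristic size, and that shared
#' anatomical profile is what homogeneity QA correlates against.
#' `sdlog = 0.2` gives a realistic ~20% between-subject coefficient of
#' variation.
#'
#' @inheritParams default_rate_map
#' @return Tibble `roi_id`, `measure`, `meanlog`, `sdlog`.
#' @export
default_baseline_map <- function(roi_spec) {
  scale_for <- c(volume = 1500, area = 500, thickness = 2.5,
                 gyrification = 25, depth = 10)
  roi_spec |>
    mutate(
      meanlog = log(ifelse(.data$stream == "vbm", 3000,
                           scale_for[.data$measure])) +
        2 * feature_u(.data$roi_id, .data$measure) - 1,
      sdlog = 0.2
    ) |>
    select("roi_id", "measure", "meanlog", "sdlog")
}

# deterministic pseudo-uniform value in [0, 1] per feature name; gives
# regions stable, reproducible characteristic scales and null rates
feature_u <- function(roi_id, measure) {
  vapply(paste(roi_id, measure), function(key) {
    h <- 0
    for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 9973
    h / 9972
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a synthetic two-group longitudinal cohort
#'
#' Simulates the measurement process the APC pipeline assumes. For each
#' subject, feature baselines are drawn log-normal; the follow-up value
#' is the multiplicative-model projection over the subject's observed
#' interval with log-normal measurement noise:
#' `x2 = x1 * (1 + q)^(dt / 365) * exp(e)`, `e ~ N(0, noise_sigma^2)`,
#' where `q` is the feature's configured group rate plus the subject's
#' progression shift (`subject_rate_sd`).
#' Observed intervals are `interval_mean_days` plus a uniform integer
#' jitter in `[-interval_jitter_days, +interval_jitter_days]`.
#' Cognitive scores are drawn at baseline per group and change by
#' `intercept + coupling * (subject mean true rate) + noise`, clipped
#' to each instrument's legal range (MMSE 0-30, CDR >= 0, FAQ 0-30,
#' NPI >= 0).
#'
#' All randomness flows through one RNG stream seeded from
#' `config$seed`, so the same configuration reproduces the cohort
#' byte-identically.
#'
#' @param config A [cohort_config()].
#' @return List of class `apc_cohort` with elements
#'   \describe{
#'     \item{measurements}{Long tibble `subject_id`, `group`,
#'       `visit_date`, `roi_id`, `measure`, `stream`, `value`; two
#'       visits per subject x feature, all values strictly positive.}
#'     \item{cognition}{Long tibble `subject_id`, `group`, `visit`
#'       (`screening`/`year1`), `instrument`, `score`.}
#'     \item{truth}{List with `features` (per group x feature:
#'       `q_true`, `is_null`) and `subjects` (`subject_id`, `group`,
#'       `mean_rate` -- the subject's realized mean annual rate across
#'       features -- plus `rate_shift` and `delta_days`).}
#'   }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by `cohort_config()`.")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  groups <- config$groups
  n <- config$n_per_group
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(2 * n)),
    group = rep(groups, each = n)
  )
  n_sub <- nrow(subjects)
  n_feat <- nrow(config$roi_spec)

  jit <- config$interval_jitter_days
  delta_days <- config$interval_mean_days +
    (if (jit > 0) sample.int(2L * jit + 1L, n_sub, replace = TRUE) -
       jit - 1L else 0L)
  baseline_date <- as.Date("2019-06-01") + 7L * (seq_len(n_sub) - 1L)
  rate_shift <- if (config$subject_rate_sd > 0) {
    rnorm(n_sub, 0, config$subject_rate_sd)
  } else {
    rep(0, n_sub)
  }
  subjects <- mutate(subjects, delta_days = as.numeric(delta_days),
                     baseline_date = baseline_date,
                     rate_shift = rate_shift)

  grid <- tidyr::crossing(subjects, config$roi_spec) |>
    left_join(config$rate_map, by = c("group", "roi_id", "measure")) |>
    left_join(config$baseline_map, by = c("roi_id", "measure")) |>
    mutate(q_true = pmax(.data$q_true + .data$rate_shift, -0.95))

  m <- nrow(grid)
  x1 <- rlnorm(m, meanlog = grid$meanlog, sdlog = grid$sdlog)
  if (config$noise_on_baseline && config$noise_sigma > 0) {
    x1 <- x1 * exp(rnorm(m, 0, config$noise_sigma))
  }
  eps <- if (config$noise_sigma > 0) rnorm(m, 0, config$noise_sigma) else 0
  x2 <- x1 * (1 + grid$q_true)^(grid$delta_days / 365) * exp(eps)

  long <- bind_rows(
    grid |>
      mutate(visit_date = .data$baseline_date, value = x1),
    grid |>
      mutate(visit_date = .data$baseline_date + .data$delta_days,
             value = x2)
  ) |>
    select("subject_id", "group", "visit_date", "roi_id", "measure",
           "stream", "value") |>
    arrange(.data$subject_id, .data$roi_id, .data$measure, .data$stream,
            .data$visit_date)

  subject_rates <- grid |>
    group_by(.data$subject_id, .data$group) |>
    summarise(mean_rate = mean(.data$q_true), .groups = "drop")

  cognition <- generate_cognition(subjects, subject_rates, config)

  feature_truth <- config$rate_map |>
    tidyr::pivot_wider(names_from = "group", values_from = "q_true") |>
    rename(q_true_case = all_of(groups[1]), q_true_ctrl = all_of(groups[2])) |>
    mutate(is_null = .data$q_true_case == .data$q_true_ctrl) |>
    left_join(distinct(config$roi_spec, .data$roi_id, .data$measure,
                       .data$stream),
              by = c("roi_id", "measure"))

  structure(
    list(
      measurements = long,
      cognition = cognition,
      truth = list(
        features = feature_truth,
        subjects = select(left_join(subject_rates,
                                    select(subjects, "subject_id",
                                           "delta_days", "rate_shift"),
                                    by = "subject_id"),
                          "subject_id", "group", "mean_rate",
                          "rate_shift", "delta_days")
      ),
      config = config
    ),
    class = "apc_cohort"
  )
}

# group-level baseline score distributions for an AD-vs-CN style study
cognition_baseline_params <- function(groups) {
  tibble(
    group = rep(groups, each = 4),
    instrument = rep(c("MMSE", "CDR_GLOBAL", "FAQ_TOTAL", "NPI_TOTAL"), 2),
    mean = c(22.76, 0.82, 15.00, 10.20, 28.70, 0.14, 1.33, 1.12),
    sd = c(2.74, 0.24, 6.18, 10.15, 3.10, 0.42, 5.09, 2.03)
  )
}

clip_score <- function(instrument, score) {
  lo <- 0
  hi <- ifelse(instrument %in% c("MMSE", "FAQ_TOTAL"), 30, Inf)
  pmin(pmax(score, lo), hi)
}

generate_cognition <- function(subjects, subject_rates, config) {
  params <- cognition_baseline_params(config$groups)
  base <- tidyr::crossing(
    select(subjects, "subject_id", "group"),
    instrument = names(config$cognition_coupling)
  ) |>
    left_join(params, by = c("group", "instrument")) |>
    left_join(select(subject_rates, "subject_id", "mean_rate"),
              by = "subject_id") |>
    arrange(.data$subject_id, .data$instrument)

  k <- nrow(base)
  base <- base |>
    mutate(
      score0 = clip_score(.data$instrument,
                          rnorm(k, .data$mean, .data$sd)),
      delta = config$cognition_intercept[.data$instrument] +
        config$cognition_coupling[.data$instrument] * .data$mean_rate +
        rnorm(k, 0, config$cognition_noise_sd[.data$instrument]),
      score1 = clip_score(.data$instrument, .data$score0 + .data$delta)
    )

  bind_rows(
    base |> mutate(visit = "screening", score = .data$score0),
    base |> mutate(visit = "year1", score = .data$score1)
  ) |>
    select("subject_id", "group", "visit", "instrument", "score") |>
    arrange(.data$subject_id, .data$instrument, .data$visit)
}

#' Generate a labelled p-value mixture for multiplicity experiments
#'
#' Draws `round(pi0 * m)` null p-values uniform on (0, 1) and the rest
#' from a one-sided z-shift alternative: `p = 1 - pnorm(z)` with
#' `z ~ N(effect, 1)`, so alternative p-values concentrate near zero
#' as `effect` grows. This is the test-bed distribution for the
#' multiple-testing module (pi0 recovery, FDR control).
#'
#' @param m Number of tests (>= 1).
#' @param pi0 True fraction of null hypotheses, in `[0, 1]`.
#' @param effect Noncentrality of the alternative z-shift (>= 0).
#' @param seed Integer seed.
#' @return Tibble with columns `p` and `is_null`.
#' @export
generate_pvalue_mixture <- function(m, pi0, effect = 3, seed = 1L) {
  if (m < 1) abort("`m` must be at least 1.")
  if (pi0 < 0 || pi0 > 1) abort("`pi0` must be in [0, 1].")
  withr::with_seed(seed, {
    m0 <- round(pi0 * m)
    m1 <- m - m0
    p0 <- runif(m0)
    p1 <- if (m1 > 0) pnorm(rnorm(m1, mean = effect), lower.tail = FALSE)
          else numeric(0)
    tibble(
      p = c(p0, p1),
      is_null = rep(c(TRUE, FALSE), c(m0, m1))
    )
  })
}
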