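#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. Either point `measurements` (and optionally `cognition`) at
#' input files / tables, or leave them `NULL` and supply a `cohort`
#' configuration to analyse a synthetic cohort.
#'
#' @param measurements Path to a measurement TSV/CSV, or a measurement
#'   tibble, or `NULL` to synthesize.
#' @param cognition Path to a cognition TSV/CSV, a tibble, or `NULL`.
#' @param cohort A [cohort_config()] used when `measurements` is
#'   `NULL`; default `cohort_config(seed = seed)`.
#' @param n_days APC normalization interval in days (default 365).
#' @param qa_k Homogeneity exclusion SD multiplier (default 2).
#' @param run_qa,run_cognition Stage toggles (default `TRUE`;
#'   cognition is skipped automatically when no scores are available).
#' @param test_variant `"pooled"` or `"welch"` (default pooled).
#' @param alpha FDR level and individual-test level (default 0.05).
#' @param family_mode Correction family scoping; see [correct_mtc()].
#' @param lambda,pi0_df Storey pi0 tuning; see [estimate_pi0()].
#' @param case,control Group labels for the sign convention of the
#'   comparisons; default taken from the cohort/groups present.
#' @param out_dir Directory for [write_bundle()]; `NULL` keeps results
#'   in memory only.
#' @param seed Integer seed used for any synthesis.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(measurements = NULL, cognition = NULL,
                            cohort = NULL, n_days = 365, qa_k = 2,
                            run_qa = TRUE, run_cognition = TRUE,
                            test_variant = c("pooled", "welch"),
                            alpha = 0.05,
                            family_mode = c("per-measure", "reproduce",
                                            "global"),
                            lambda = seq(0.05, 0.90, by = 0.05),
                            pi0_df = 3, case = NULL, control = NULL,
                            out_dir = NULL, seed = 1L) {
  test_variant <- match.arg(test_variant)
  family_mode <- match.arg(family_mode)
  if (n_days <= 0) abort("`n_days` must be strictly positive.")
  if (qa_k <= 0) abort("`qa_k` must be strictly positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(measurements = measurements, cognition = cognition,
         cohort = cohort, n_days = n_days, qa_k = qa_k, run_qa = run_qa,
         run_cognition = run_cognition, test_variant = test_variant,
         alpha = alpha, family_mode = family_mode, lambda = lambda,
         pi0_df = pi0_df, case = case, control = control,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Scalar fields round-trip unchanged. A `cohort` entry is stored as
#' its scalar generative parameters; table-valued parameters
#' (`roi_spec`, `rate_map`, `baseline_map`) are reconstructed from the
#' package defaults on read, so a fully custom panel should be driven
#' from R rather than from a config file.
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()]: a `pipeline_config`;
#'   [write_pipeline_config()]: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    ch <- raw$cohort
    cohort_args <- ch[intersect(names(ch), names(formals(cohort_config)))]
    for (nm in c("cognition_coupling", "cognition_intercept",
                 "cognition_noise_sd")) {
      if (!is.null(cohort_args[[nm]])) {
        cohort_args[[nm]] <- unlist(cohort_args[[nm]])
      }
    }
    if (!is.null(cohort_args$groups)) {
      cohort_args$groups <- unlist(cohort_args$groups)
    }
    cohort <- do.call(cohort_config, cohort_args)
  }
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  args$cohort <- cohort
  if (!is.null(args$lambda)) args$lambda <- unlist(args$lambda)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$measurements <- if (is.character(out$measurements)) out$measurements
  out$cognition <- if (is.character(out$cognition)) out$cognition
  if (!is.null(out$cohort)) {
    ch <- unclass(out$cohort)
    ch$roi_spec <- NULL
    ch$rate_map <- NULL
    ch$baseline_map <- NULL
    ch$cognition_coupling <- as.list(ch$cognition_coupling)
    ch$cognition_intercept <- as.list(ch$cognition_intercept)
    ch$cognition_noise_sd <- as.list(ch$cognition_noise_sd)
    out$cohort <- ch
  }
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full longitudinal morphometry analysis
#'
#' Stage order: (synthesize or load inputs) -> homogeneity QA ->
#' APC annualization -> per-feature group comparison -> multiplicity
#' correction -> cognition correlation. QA exclusions propagate to
#' every downstream stage. The returned bundle carries a manifest
#' (configuration hash, seed, row counts, exclusion and drop events)
#' from which every output table is regenerable.
#'
#' @param config A [pipeline_config()].
#' @return List of class `report_bundle` with elements `qa`, `apc`,
#'   `comparison`, `mtc`, `correlations`, `truth` (synthetic inputs
#'   only) and `manifest`. If `config$out_dir` is set the bundle is
#'   also written there via [write_bundle()].
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 42)
#' bundle <- run_pipeline(cfg)
#' glance(bundle$mtc)
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created by `pipeline_config()`.")
  }
  truth <- NULL
  if (is.null(config$measurements)) {
    cohort_cfg <- config$cohort %||% cohort_config(seed = config$seed)
    cohort <- generate_cohort(cohort_cfg)
    measurements <- cohort$measurements
    cognition <- cohort$cognition
    truth <- cohort$truth
    groups_cc <- cohort_cfg$groups
  } else {
    measurements <- if (is.character(config$measurements)) {
      read_measurements(config$measurements)
    } else as_tibble(config$measurements)
    cognition <- if (is.character(config$cognition)) {
      read_cognition(config$cognition)
    } else if (!is.null(config$cognition)) {
      as_tibble(config$cognition)
    }
    groups_cc <- sort(unique(measurements$group))
  }
  case <- config$case %||% groups_cc[1]
  control <- config$control %||% setdiff(groups_cc, case)[1]

  qa <- NULL
  retained <- unique(measurements$subject_id)
  if (isTRUE(config$run_qa)) {
    qa <- qa_homogeneity(measurements, k = config$qa_k)
    retained <- qa$subject_id[!qa$excluded]
    measurements <- filter(measurements, .data$subject_id %in% retained)
  }

  apc_tbl <- apc_table(measurements, n_days = config$n_days)
  comparison <- compare_all(apc_tbl, case = case, control = control,
                            variant = config$test_variant,
                            alpha = config$alpha)
  mtc <- correct_mtc(comparison, family_mode = config$family_mode,
                     alpha = config$alpha, lambda = config$lambda,
                     df = config$pi0_df)

  correlations <- NULL
  if (isTRUE(config$run_cognition) && !is.null(cognition)) {
    deltas <- score_change(cognition)
    correlations <- correlate_rois(apc_tbl, deltas, subjects = retained)
  }

  # the hash covers everything that determines the numbers; where the
  # bundle is written does not
  hash_cfg <- unclass(config)
  hash_cfg$out_dir <- NULL
  manifest <- list(
    config_hash = rlang::hash(hash_cfg),
    seed = config$seed,
    case = case, control = control,
    n_subjects_input = length(unique(c(measurements$subject_id,
                                       if (!is.null(qa)) qa$subject_id))),
    n_subjects_retained = length(retained),
    n_excluded_qa = if (!is.null(qa)) sum(qa$excluded) else 0L,
    n_apc_records = nrow(apc_tbl),
    n_features = nrow(comparison),
    n_sig_unc = sum(comparison$sig_unc),
    n_sig_bh = sum(mtc$table$sig_bh),
    n_sig_q = sum(mtc$table$sig_q),
    alpha = config$alpha,
    n_days = config$n_days,
    family_mode = config$family_mode,
    test_variant = config$test_variant
  )

  bundle <- structure(
    list(qa = qa, apc = apc_tbl, comparison = comparison, mtc = mtc,
         correlations = correlations, truth = truth, manifest = manifest),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  m <- x$manifest
  cat("Longitudinal morphometry report bundle\n")
  cat("  subjects: ", m$n_subjects_retained, " retained (",
      m$n_excluded_qa, " excluded by QA)\n", sep = "")
  cat("  features: ", m$n_features, "; APC records: ", m$n_apc_records,
      "\n", sep = "")
  cat("  significant at alpha = ", m$alpha, ": ", m$n_sig_unc,
      " uncorrected, ", m$n_sig_bh, " BH, ", m$n_sig_q, " Storey\n",
      sep = "")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One TSV per stage plus a JSON sidecar with the per-family pi0
#' traces, applicability diagnostics and the run manifest. Output is
#' deterministic: the same bundle writes byte-identical files.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num_cols_full <- function(tbl) {
    tbl <- as_tibble(tbl)
    num <- vapply(tbl, is.numeric, logical(1))
    tbl[num] <- lapply(tbl[num], format_full)
    tbl
  }
  if (!is.null(bundle$qa)) {
    readr::write_tsv(num_cols_full(tidy(bundle$qa)),
                     file.path(dir, "qa.tsv"))
  }
  readr::write_tsv(num_cols_full(bundle$apc), file.path(dir, "apc.tsv"))
  readr::write_tsv(num_cols_full(as_tibble(bundle$comparison)),
                   file.path(dir, "comparison.tsv"))
  readr::write_tsv(num_cols_full(tidy(bundle$mtc)),
                   file.path(dir, "mtc.tsv"))
  if (!is.null(bundle$correlations)) {
    readr::write_tsv(num_cols_full(bundle$correlations),
                     file.path(dir, "correlations.tsv"))
  }
  sidecar <- list(
    manifest = bundle$manifest,
    families = lapply(bundle$mtc$families, function(fam) {
      list(
        pi0 = unclass(fam$pi0),
        conditions = unclass(fam$conditions),
        recommended = fam$recommended
      )
    })
  )
  jsonlite::write_json(sidecar, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
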