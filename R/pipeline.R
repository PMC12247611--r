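# End-to-end pipeline: simulate (or read) -> split -> fit -> score ->
# flag -> compare -> report. Every stage is driven by one config list
# and a single seed, and the manifest written alongside the report is
# sufficient to regenerate every artifact.

#' Pipeline configuration
#'
#' @param n_subjects Cohort size to simulate (ignored when `idp_table`
#'   is given).
#' @param idp_table Optional path to an existing cohort CSV/TSV; when
#'   `NULL` a cohort is simulated with [default_artefact_specs()]
#'   contamination.
#' @param idps Phenotype columns to model; `NULL` = autodetect.
#' @param test_n Held-out test-set size; `NULL` uses `test_fraction`.
#' @param test_fraction Fraction held out when `test_n` is `NULL`
#'   (default 1/3).
#' @param outlier_threshold Deviation threshold in SDs (default 7).
#' @param thresholds PR-sweep z thresholds (default `c(3,4,5,6,7)`).
#' @param rater_reliability Simulated rater reliability (default 0.9).
#' @param output_dir Directory to write the report to; `NULL` = don't
#'   write.
#' @param seed Master seed for the whole run.
#' @return A named list of class `qc_pipeline_config`.
#' @export
qc_pipeline_config <- function(n_subjects = 2000, idp_table = NULL,
                               idps = NULL, test_n = NULL,
                               test_fraction = 1 / 3,
                               outlier_threshold = 7,
                               thresholds = c(3, 4, 5, 6, 7),
                               rater_reliability = 0.9,
                               output_dir = NULL, seed = 1) {
  check_number(outlier_threshold, "outlier_threshold", lower = 0,
               strict_lower = TRUE)
  if (any(thresholds <= 0)) abort("`thresholds` must be positive.")
  if (!is.null(test_n)) check_number(test_n, "test_n", lower = 1)
  check_number(test_fraction, "test_fraction", lower = 0, upper = 1)
  structure(list(n_subjects = n_subjects, idp_table = idp_table,
                 idps = idps, test_n = test_n,
                 test_fraction = test_fraction,
                 outlier_threshold = outlier_threshold,
                 thresholds = thresholds,
                 rater_reliability = rater_reliability,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "qc_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file whose
#'   keys match the arguments of [qc_pipeline_config()].
#' @return A `qc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(qc_pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(qc_pipeline_config, raw)
}

#' Run the full normative-modelling QC pipeline
#'
#' Simulates (or reads) a cohort, splits it into training and test
#' subjects, fits one warped-BLR normative model per phenotype on the
#' training set, computes held-out deviation z-scores, flags extreme
#' outliers, and runs the comparison battery: inter-rater ICC3k,
#' class-balanced SVM evaluation of the quantitative-QC descriptors
#' against each rater, the PR threshold sweep, quantitative-QC outlier
#' frequencies and the six-measure QC correlation matrix. Deterministic
#' given the config: two runs with the same config produce
#' byte-identical reports.
#'
#' @param config A [qc_pipeline_config()], or a path readable by
#'   [read_pipeline_config()].
#' @return The report: a named list with blocks `manifest`,
#'   `fit_statistics`, `zscores`, `outliers`, `outlier_summary`,
#'   `icc`, `svm`, `pr`, `qqc`, `correlation`. Written to
#'   `config$output_dir` when set.
#' @export
run_qc_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "qc_pipeline_config"))

  if (is.null(config$idp_table)) {
    spec <- cohort_spec(config$n_subjects,
                        contamination = default_artefact_specs(),
                        rater_reliability = config$rater_reliability,
                        seed = config$seed)
    cohort <- simulate_cohort(spec)
  } else {
    cohort <- read_idp_table(config$idp_table)
  }
  idps <- config$idps %||% intersect(default_idp_names(), names(cohort))
  if (length(idps) == 0L) abort("No phenotype columns to model.")

  n <- nrow(cohort)
  test_n <- config$test_n %||% max(1L, floor(config$test_fraction * n))
  test_idx <- run_seeded(config$seed + 1L, sample(n, min(test_n, n - 1L)))
  train <- cohort[-test_idx, , drop = FALSE]
  test <- cohort[test_idx, , drop = FALSE]

  fits <- fit_normative_set(train, idps = idps, seed = config$seed)
  fstats <- fit_statistics_set(fits, test)
  zs <- zscore_table(fits, test)
  ot <- flag_outliers(zs, threshold = config$outlier_threshold)
  if ("true_category" %in% names(test)) {
    truth_labels <- test |>
      dplyr::filter(.data$true_category != "clean") |>
      dplyr::select("subject_id", category = "true_category")
    ot <- suppressWarnings(assign_categories(ot, truth_labels))
  }
  freq <- outlier_frequency(ot)

  icc <- if (all(c("rater1", "rater2") %in% names(test))) {
    icc3k(cbind(test$rater1, test$rater2))
  } else NA_real_

  qqc_cols <- intersect(qqc_descriptor_defaults()$name, names(test))
  svm_block <- NULL
  svm_dec <- NULL
  if (length(qqc_cols) > 0L && all(c("rater1", "rater2") %in% names(test))) {
    svm_block <- lapply(c(rater1 = "rater1", rater2 = "rater2"), function(r) {
      y <- binarize_scores(test[[r]])
      if (sum(y == 1L) >= 5L && sum(y == 0L) >= 5L) {
        ev <- balanced_svm_evaluation(test[qqc_cols], test[[r]],
                                      seed = config$seed)
        list(per_subsample = ev$per_subsample, summary = ev$summary)
      } else NULL
    })
    y1 <- binarize_scores(test$rater1)
    if (sum(y1 == 1L) >= 5L) {
      svm_dec <- svm_decision_values(test[qqc_cols], test$rater1,
                                     seed = config$seed)
    }
  }

  nm_score <- zs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(max_abs_z = max(abs(.data$z)), .groups = "drop")
  nm_score <- nm_score[match(test$subject_id, nm_score$subject_id), ]
  pr_block <- NULL
  if ("rater1" %in% names(test)) {
    truth <- binarize_scores(test$rater1)
    if (sum(truth) > 0L) {
      sweep <- pr_threshold_sweep(nm_score$max_abs_z, truth,
                                  thresholds = config$thresholds,
                                  svm_scores = svm_dec)
      pr_block <- sweep |> dplyr::select("method", "threshold", "auc")
    }
  }

  qqc_freq <- if (length(qqc_cols) > 0L) {
    qqc_outlier_frequency(test[c("subject_id", qqc_cols)])
  } else NULL

  corr <- NULL
  if (all(c("t1_dwi_discrepancy", "fa_template_discrepancy", "snr_b0",
            "rater1") %in% names(test)) && !is.null(qqc_freq)) {
    measures <- tibble(
      t1_discrepancy = test$t1_dwi_discrepancy,
      fa_dwi_discrepancy = test$fa_template_discrepancy,
      snr = test$snr_b0,
      nm_outlier_freq = freq$per_subject$n_flagged[
        match(test$subject_id, freq$per_subject$subject_id)],
      qqc_outlier_freq = qqc_freq$n_flagged,
      visual_qc_score = as.numeric(test$rater1))
    corr <- qc_correlation_matrix(measures)
  }

  report <- list(
    manifest = list(package = "normqc",
                    version = as.character(packageVersion("normqc")),
                    config = unclass(config)[!vapply(unclass(config),
                                                     is.null, logical(1))],
                    n_total = n, n_train = nrow(train), n_test = nrow(test),
                    idps = idps),
    fit_statistics = fstats,
    model_diagnostics = fits |>
      dplyr::select(-"model"),
    zscores = zs,
    outliers = as_tibble(ot),
    outlier_summary = freq$per_subject,
    outlier_per_idp = freq$per_idp,
    icc = icc,
    svm = svm_block,
    pr = pr_block,
    qqc = list(mean_outlier_frequency =
                 if (is.null(qqc_freq)) NA_real_ else mean(qqc_freq$n_flagged)),
    correlation = corr)

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
    write_models_json(fits, file.path(config$output_dir, "models.json"))
    jsonlite::write_json(report$manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
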