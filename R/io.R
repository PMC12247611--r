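# Readers and writers: cohort tables (CSV/TSV), fitted models (JSON),
# z-scores and reports.

#' Read a per-subject phenotype table
#'
#' Reads a CSV or TSV (delimiter sniffed from the extension) with a
#' header row; `subject_id` and `age` columns are mandatory, subject
#' ids must be unique, and phenotype columns must parse as numeric.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param idps Optional character vector of phenotype columns that must
#'   be present and numeric; defaults to all columns other than
#'   `subject_id`, `age`, `sex`, `true_category`, `rater1`, `rater2`.
#' @return A tibble, one row per subject.
#' @export
read_idp_table <- function(path, idps = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  reader <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("subject_id", "age")) {
    if (!col %in% names(x)) {
      abort(sprintf("Mandatory column `%s` missing from %s.", col, path))
    }
  }
  dup <- x$subject_id[duplicated(x$subject_id)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate subject_id: %s", paste(unique(dup), collapse = ", ")))
  }
  if (!is.numeric(x$age) || anyNA(x$age)) {
    abort("`age` must be numeric with no missing values.")
  }
  if (is.null(idps)) {
    idps <- setdiff(names(x), c("subject_id", "age", "sex",
                                "true_category", "rater1", "rater2"))
  }
  for (col in idps) {
    if (!col %in% names(x)) {
      abort(sprintf("Phenotype column `%s` missing.", col))
    }
    if (!is.numeric(x[[col]])) {
      abort(sprintf("Phenotype column `%s` is not numeric.", col))
    }
  }
  x
}

#' Write a cohort table as CSV
#'
#' Plain UTF-8 CSV with a header row and `.` decimal separator; the
#' generating seed (if the table carries one) is written alongside as
#' `<path>.meta.json`.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  seed <- attr(cohort, "seed")
  if (!is.null(seed)) {
    jsonlite::write_json(list(seed = seed, n_subjects = nrow(cohort)),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

model_to_list <- function(m) {
  list(idp = m$idp, age_col = m$age_col, warp_type = m$warp_type,
       standardize = m$standardize,
       basis = list(degree = m$basis$degree, knots = m$basis$knots,
                    domain = m$basis$domain, n_fun = m$basis$n_fun),
       warp = unclass(m$warp),
       alpha = m$alpha, beta = m$beta, m = m$m, A = m$A,
       n = m$n, nll = m$nll, converged = m$converged,
       n_restarts = m$n_restarts, seed = m$seed)
}

list_to_model <- function(l) {
  basis <- structure(
    list(degree = as.integer(l$basis$degree),
         knots = as.numeric(l$basis$knots),
         interior = as.numeric(l$basis$knots[-c(1, length(l$basis$knots))]),
         domain = as.numeric(l$basis$domain),
         n_fun = as.integer(l$basis$n_fun)),
    class = "nm_basis")
  A <- matrix(unlist(l$A), nrow = basis$n_fun)
  structure(
    list(basis = basis,
         warp = do.call(warp_params, l$warp),
         warp_type = l$warp_type, standardize = l$standardize,
         alpha = l$alpha, beta = l$beta,
         m = as.numeric(unlist(l$m)), A = A, chol_A = chol(A),
         n = l$n, nll = l$nll, converged = l$converged,
         n_restarts = l$n_restarts, seed = l$seed,
         idp = l$idp, age_col = l$age_col),
    class = "normative_model")
}

#' Serialise fitted normative models to JSON
#'
#' Writes every scalar, vector and matrix of each fitted model (basis
#' definition, warp parameters, weight posterior, precisions, seeds) to
#' a single library-agnostic JSON file; [read_models_json()] restores
#' working model objects.
#'
#' @param fits A single `normative_model` or the tibble from
#'   [fit_normative_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(fits, path) {
  models <- if (inherits(fits, "normative_model")) list(fits) else fits$model
  payload <- lapply(models, model_to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models_json
#' @return `read_models_json()`: a list of `normative_model` objects.
#' @export
read_models_json <- function(path) {
  lapply(jsonlite::read_json(path), list_to_model)
}

#' Write a QC comparison report
#'
#' Writes the report produced by [run_qc_pipeline()] (or assembled by
#' hand) into a directory: `report.json` with every result block, plus
#' CSV tables for z-scores, outliers and per-subject summaries when
#' present.
#'
#' @param report Named list of result blocks.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("zscores", "outliers", "outlier_summary", "fit_statistics")
  for (nm in intersect(tables, names(report))) {
    readr::write_csv(as.data.frame(report[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), progress = FALSE)
  }
  json_part <- report[setdiff(names(report), c("zscores", "outliers"))]
  json_part <- lapply(json_part, function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  })
  jsonlite::write_json(json_part, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(dir)
}
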