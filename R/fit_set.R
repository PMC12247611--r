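#' Fit normative models for a set of phenotypes
#'
#' Maps [fit_normative()] over several phenotype columns of a cohort
#' table, returning one row per phenotype with the fitted model in a
#' list-column alongside its [glance()] diagnostics.
#'
#' @param data Cohort data frame (one row per subject).
#' @param idps Character vector of phenotype column names; defaults to
#'   every column in [default_idp_names()] present in `data`.
#' @param age Name of the age column.
#' @inheritParams fit_normative
#' @return A tibble with columns `idp`, `model` (list-column) and the
#'   glance diagnostics of each fit.
#' @export
fit_normative_set <- function(data, idps = NULL, age = "age",
                              warp = c("sinharcsinh", "identity"),
                              standardize = c("fixed", "none", "learn"),
                              n_knots = 5, n_restarts = 3, seed = 1) {
  warp <- match.arg(warp)
  standardize <- match.arg(standardize)
  if (is.null(idps)) {
    idps <- intersect(default_idp_names(), names(data))
    if (length(idps) == 0L) {
      abort("No phenotype columns found; pass `idps` explicitly.")
    }
  }
  missing_cols <- setdiff(c(idps, age), names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  models <- purrr::map(idps, function(nm) {
    m <- fit_normative_impl(data[[age]], data[[nm]], warp_type = warp,
                            standardize = standardize,
                            n_restarts = n_restarts, seed = seed,
                            n_knots = n_knots)
    m$idp <- nm
    m$age_col <- age
    m
  })
  diag <- purrr::map_dfr(models, glance)
  dplyr::bind_cols(tibble(idp = idps, model = models), diag)
}

#' Long table of deviation z-scores for a set of fitted models
#'
#' @param fits Output of [fit_normative_set()].
#' @param data Data frame to score (must contain `subject_id`, the age
#'   column and every fitted phenotype column).
#' @return A long tibble with columns `subject_id`, `idp`, `z`.
#' @export
zscore_table <- function(fits, data) {
  if (!"subject_id" %in% names(data)) {
    abort("`data` must contain a `subject_id` column.")
  }
  purrr::map2_dfr(fits$idp, fits$model, function(nm, m) {
    tibble(subject_id = data$subject_id, idp = nm,
           z = compute_zscores(m, data)$z)
  })
}

#' Fit statistics across a set of fitted models
#'
#' @inheritParams zscore_table
#' @return One row per phenotype: output of [fit_statistics()].
#' @export
fit_statistics_set <- function(fits, data) {
  purrr::map_dfr(fits$model, fit_statistics, data = data)
}
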