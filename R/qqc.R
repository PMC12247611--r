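# Quantitative-QC descriptor screening and the QC-measure correlation
# matrix.

#' Quantitative-QC outlier frequency
#'
#' Flags each descriptor value lying more than `threshold_sd` column
#' standard deviations from its column mean (two-sided by default) and
#' counts flags per subject across descriptors. Zero-variance columns
#' are excluded with a warning.
#'
#' @param qqc Data frame of numeric descriptor columns (a `subject_id`
#'   column, if present, is carried through, not screened).
#' @param threshold_sd Positive threshold in SD units (default 2).
#' @param two_sided Flag both tails (default). One-sided flags the
#'   upper tail only, for quality-signed descriptors.
#' @return A tibble with `subject_id` (if supplied) and `n_flagged`;
#'   the per-column flag matrix is attached as attribute `flags`.
#' @export
qqc_outlier_frequency <- function(qqc, threshold_sd = 2, two_sided = TRUE) {
  check_number(threshold_sd, "threshold_sd", lower = 0, strict_lower = TRUE)
  check_flag(two_sided, "two_sided")
  ids <- qqc[["subject_id"]]
  x <- qqc[, setdiff(names(qqc), "subject_id"), drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("All descriptor columns must be numeric.")
  }
  sds <- vapply(x, sd, numeric(1))
  dead <- names(x)[!is.finite(sds) | sds == 0]
  if (length(dead) > 0L) {
    warn(sprintf("Excluding zero-variance descriptor(s): %s",
                 paste(dead, collapse = ", ")))
    x <- x[, setdiff(names(x), dead), drop = FALSE]
  }
  flags <- vapply(x, function(col) {
    d <- (col - mean(col)) / sd(col)
    if (two_sided) abs(d) > threshold_sd else d > threshold_sd
  }, logical(nrow(x)))
  flags <- matrix(flags, nrow = nrow(x),
                  dimnames = list(NULL, names(x)))
  out <- tibble(n_flagged = as.integer(rowSums(flags)))
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble(subject_id = ids), out)
  attr(out, "flags") <- flags
  out
}

#' Correlation matrix of QC measures
#'
#' Pairwise Pearson correlations between QC summary measures — by
#' convention the six columns: T1 discrepancy, FA-vs-DWI discrepancy,
#' SNR, normative-modelling outlier frequency, quantitative-QC outlier
#' frequency, and visual QC score. Zero-variance columns yield `NA`
#' entries (with a warning) rather than an error.
#'
#' @param measures Data frame of numeric columns, at least 3 rows.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
qc_correlation_matrix <- function(measures) {
  x <- as.data.frame(measures)
  if (nrow(x) < 3L) abort("Need at least 3 rows.")
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("All measure columns must be numeric.")
  }
  if (any(!is.finite(as.matrix(x)))) abort("Measures must be finite.")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    warn(sprintf("Zero-variance measure(s): %s; correlations set to NA.",
                 paste(names(x)[sds == 0], collapse = ", ")))
  }
  m <- suppressWarnings(cor(as.matrix(x)))
  diag(m) <- 1
  m
}
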