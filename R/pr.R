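# Precision-recall evaluation of subject-level artefact scores against
# binary ground truth (rare positive class, so PR rather than ROC).

#' Precision-recall curve and area
#'
#' Computes the precision-recall curve over all score cut-points
#' (tied scores grouped at one cut-point) and its area by step-wise
#' summation `AUC = sum_i (R_i - R_{i-1}) P_i` — no trapezoidal
#' interpolation, which is optimistic in PR space. The baseline AUC of
#' an uninformative score equals the positive-class prevalence.
#'
#' @param scores Numeric vector; larger = more likely positive.
#' @param truth Binary vector (0/1 or logical) with at least one
#'   positive.
#' @return A tibble (`cutoff`, `precision`, `recall`), one row per
#'   distinct cut-point in decreasing score order, with the area stored
#'   in attribute `auc`.
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth)) {
    abort("`scores` and `truth` must have equal length.")
  }
  if (any(!is.finite(scores))) abort("`scores` must be finite.")
  P <- sum(truth)
  if (P == 0L) abort("`truth` must contain at least one positive.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # last index of each tie group = one cut-point per distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  pp <- seq_along(s)[last]
  out <- tibble(cutoff = s[last], precision = tp / pp, recall = tp / P)
  attr(out, "auc") <- sum(diff(c(0, out$recall)) * out$precision)
  out
}

#' @rdname pr_curve
#' @return `pr_auc()`: the area as a single number.
#' @export
pr_auc <- function(scores, truth) {
  attr(pr_curve(scores, truth), "auc")
}

#' Precision-recall sweep over deviation thresholds
#'
#' Evaluates the normative-modelling outlier rule at several z-score
#' thresholds against binary ground truth (e.g. severe visual-QC
#' score). At threshold t a subject's score is the binary indicator
#' `max|z| > t`, whose PR curve is the step curve through that
#' operating point; the continuous `max|z|` ranking and, optionally, a
#' continuous classifier score (e.g. SVM decision values) are evaluated
#' on the same footing.
#'
#' @param nm_scores Per-subject continuous deviation score, typically
#'   `max |z|` across phenotypes.
#' @param truth Binary ground-truth labels, at least one positive.
#' @param thresholds z-score thresholds to binarise at (default
#'   `c(3, 4, 5, 6, 7)`).
#' @param svm_scores Optional per-subject continuous classifier scores.
#' @return A tibble with one row per evaluated score (`method`,
#'   `threshold`, `auc`, `curve` list-column of [pr_curve()] outputs).
#' @export
pr_threshold_sweep <- function(nm_scores, truth,
                               thresholds = c(3, 4, 5, 6, 7),
                               svm_scores = NULL) {
  if (any(thresholds <= 0)) abort("`thresholds` must be positive.")
  rows <- lapply(thresholds, function(t) {
    cv <- pr_curve(as.numeric(nm_scores > t), truth)
    tibble(method = sprintf("nm_z_gt_%g", t), threshold = t,
           auc = attr(cv, "auc"), curve = list(cv))
  })
  cv <- pr_curve(nm_scores, truth)
  rows <- c(rows, list(tibble(method = "nm_max_abs_z",
                              threshold = NA_real_,
                              auc = attr(cv, "auc"), curve = list(cv))))
  if (!is.null(svm_scores)) {
    cv <- pr_curve(svm_scores, truth)
    rows <- c(rows, list(tibble(method = "svm", threshold = NA_real_,
                                auc = attr(cv, "auc"), curve = list(cv))))
  }
  dplyr::bind_rows(rows)
}
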