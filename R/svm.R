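# Class-balanced, repeated-subsample, cross-validated linear SVM
# evaluation of quantitative-QC descriptors against visual-QC labels.

binarize_scores <- function(labels) {
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  if (!all(labels %in% c(1, 2, 3))) {
    abort("`labels` must be visual scores in {1,2,3} or binary 0/1.")
  }
  # scores 1 and 2 = acceptable (0); 3 = not acceptable (1)
  as.integer(labels == 3)
}

stratified_folds <- function(y, n_folds, max_redraw = 20L) {
  for (i in seq_len(max_redraw)) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(y[fold != f])) == 2L
    }, logical(1)))
    if (ok) return(fold)
    inform("Degenerate fold split (single-class training fold); redrawing.")
  }
  abort("Could not draw a fold split with both classes in every training fold.")
}

#' Class-balanced cross-validated linear SVM evaluation
#'
#' Evaluates how well quantitative-QC descriptors predict the binarised
#' visual-QC label (scores 1--2 = acceptable, 3 = not acceptable). The
#' rare not-acceptable class is kept whole while the acceptable class
#' is randomly downsampled to match it; this balancing is repeated for
#' `n_subsamples` draws, each evaluated by stratified `n_folds`-fold
#' cross-validation of a linear SVM (unit-variance feature scaling,
#' cost `cost`), pooling held-out predictions within a draw. The
#' summary is the mean (and SD) of accuracy, sensitivity and
#' specificity across draws. Deterministic given `seed`.
#'
#' @param features Data frame of numeric descriptor columns (a
#'   `subject_id` column is ignored).
#' @param labels Per-subject visual scores in `{1,2,3}` (binarised as
#'   above) or already-binary 0/1 labels.
#' @param n_subsamples Number of balancing draws (default 20).
#' @param n_folds Cross-validation folds (default 5).
#' @param cost SVM regularisation constant (default 1).
#' @param seed Seed for subsampling and fold draws (default 1).
#' @return A list of class `nm_svm_eval`: `per_subsample` tibble
#'   (`subsample`, `accuracy`, `sensitivity`, `specificity`),
#'   `summary` tibble (mean and SD per metric), and the per-subsample
#'   pooled decision values in `decision_values`.
#' @export
balanced_svm_evaluation <- function(features, labels, n_subsamples = 20,
                                    n_folds = 5, cost = 1, seed = 1) {
  check_number(n_subsamples, "n_subsamples", lower = 1)
  check_number(n_folds, "n_folds", lower = 2)
  x <- as.data.frame(features)
  x$subject_id <- NULL
  if (!all(vapply(x, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(x)))) {
    abort("`features` must be finite numeric columns.")
  }
  y <- binarize_scores(labels)
  if (length(y) != nrow(x)) {
    abort("`labels` must have one entry per feature row.")
  }
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  if (length(i1) == 0L || length(i0) == 0L) {
    abort("Both classes must be present after binarisation.")
  }
  run_seeded(seed, {
    per <- purrr::map_dfr(seq_len(n_subsamples), function(s) {
      take0 <- sample(i0, min(length(i1), length(i0)))
      idx <- c(i1, take0)
      xs <- x[idx, , drop = FALSE]
      ys <- factor(y[idx], levels = c(0, 1))
      fold <- stratified_folds(as.integer(as.character(ys)), n_folds)
      pred <- factor(rep(NA_character_, length(ys)), levels = c("0", "1"))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        fit <- e1071::svm(xs[tr, , drop = FALSE], ys[tr],
                          kernel = "linear", cost = cost, scale = TRUE)
        pred[!tr] <- predict(fit, xs[!tr, , drop = FALSE])
      }
      tp <- sum(pred == "1" & ys == "1"); fn <- sum(pred == "0" & ys == "1")
      tn <- sum(pred == "0" & ys == "0"); fp <- sum(pred == "1" & ys == "0")
      tibble(subsample = s,
             accuracy = (tp + tn) / length(ys),
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp))
    })
    summary <- per |>
      tidyr::pivot_longer(-"subsample", names_to = "metric") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       .groups = "drop")
    structure(list(per_subsample = per, summary = summary,
                   n_subsamples = n_subsamples, n_folds = n_folds),
              class = "nm_svm_eval")
  })
}

#' @export
print.nm_svm_eval <- function(x, ...) {
  cat(sprintf("<nm_svm_eval> %d subsamples x %d-fold CV\n",
              x$n_subsamples, x$n_folds))
  print(x$summary)
  invisible(x)
}

#' Cross-validated SVM decision values for the full sample
#'
#' Convenience helper for the PR comparison: returns a continuous
#' decision value per subject from stratified cross-validation of a
#' linear SVM on the full (unbalanced) sample, with class weights
#' inversely proportional to class size.
#'
#' @inheritParams balanced_svm_evaluation
#' @return Numeric vector of decision values (larger = more likely
#'   not-acceptable).
#' @export
svm_decision_values <- function(features, labels, n_folds = 5, cost = 1,
                                seed = 1) {
  x <- as.data.frame(features)
  x$subject_id <- NULL
  y <- binarize_scores(labels)
  yf <- factor(y, levels = c(0, 1))
  run_seeded(seed, {
    fold <- stratified_folds(y, n_folds)
    dec <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "linear",
                        cost = cost, scale = TRUE,
                        class.weights = c("0" = 1 / sum(y[tr] == 0),
                                          "1" = 1 / sum(y[tr] == 1)))
      dv <- attr(predict(fit, x[!tr, , drop = FALSE],
                         decision.values = TRUE), "decision.values")
      # orient so larger means class "1" (e1071 signs the value toward
      # the first class in the "a/b" column label)
      sign_flip <- if (colnames(dv)[1] == "0/1") -1 else 1
      dec[!tr] <- sign_flip * dv[, 1]
    }
    dec
  })
}
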