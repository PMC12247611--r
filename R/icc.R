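#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects, average-measures, consistency intraclass
#' correlation, computed from the two-way ANOVA mean squares:
#' `ICC3k = (MS_subjects - MS_error) / MS_subjects`, where `MS_error`
#' is the subject-by-rater interaction mean square. This is the
#' standard inter-rater reliability for a fixed panel of k raters whose
#' average rating is the measurement of interest.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows and
#'   raters in columns (at least 3 subjects, at least 2 raters).
#' @return A single number in `(-Inf, 1]`; `NA` (with a warning) when
#'   the between-subject variance is zero and the coefficient is
#'   undefined.
#' @examples
#' r <- cbind(rater1 = c(1, 2, 3, 2, 1, 3), rater2 = c(1, 3, 3, 2, 2, 3))
#' icc3k(r)
#' @export
icc3k <- function(ratings) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) abort("`ratings` must be numeric.")
  if (anyNA(x)) abort("`ratings` must be complete (no missing values).")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) abort("Need at least 3 subjects.")
  if (k < 2L) abort("Need at least 2 raters.")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (!is.finite(ms_rows) || ms_rows <= 0) {
    warn("Zero between-subject variance; ICC3k undefined.")
    return(NA_real_)
  }
  (ms_rows - ms_err) / ms_rows
}
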