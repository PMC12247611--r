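# Extreme-deviation flagging: |z| above threshold in any phenotype
# marks a subject as a normative-modelling outlier.

#' Flag extreme deviation z-scores
#'
#' A subject-phenotype pair is flagged when `|z|` strictly exceeds the
#' threshold (default 7 standard deviations, two-sided: artefacts can
#' bias a phenotype in either direction). Subjects flagged in at least
#' one phenotype form the unique-outlier set. `NaN`/`NA` z-scores are
#' refused, naming the offending pair, rather than silently dropped.
#'
#' @param z Long tibble with columns `subject_id`, `idp`, `z` (as from
#'   [zscore_table()]).
#' @param threshold Positive flagging threshold in SD units (default 7).
#' @param two_sided Flag `|z| > threshold` (default) rather than
#'   `z > threshold`.
#' @return An `outlier_table`: the input plus a logical `flagged` column
#'   and a `category` column (`"unreviewed"` for flagged subjects until
#'   [assign_categories()] is used, `NA` otherwise); `threshold` kept as
#'   an attribute.
#' @export
flag_outliers <- function(z, threshold = 7, two_sided = TRUE) {
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  check_flag(two_sided, "two_sided")
  req <- c("subject_id", "idp", "z")
  if (!all(req %in% names(z))) {
    abort("`z` must have columns subject_id, idp, z.")
  }
  bad <- which(!is.finite(z$z))
  if (length(bad) > 0L) {
    abort(sprintf("Non-finite z-score for subject %s, phenotype %s.",
                  z$subject_id[bad[1]], z$idp[bad[1]]))
  }
  out <- as_tibble(z)
  out$flagged <- if (two_sided) abs(out$z) > threshold else out$z > threshold
  out$category <- ifelse(out$flagged, "unreviewed", NA_character_)
  attr(out, "threshold") <- threshold
  class(out) <- c("outlier_table", class(out))
  out
}

#' Outlier frequency marginals
#'
#' Counts how often each subject is flagged across phenotypes and how
#' many subjects each phenotype flags. Subjects flagged in at least two
#' phenotypes are marked `multi_idp`.
#'
#' @param table An `outlier_table` from [flag_outliers()].
#' @return A list with tibbles `per_subject` (`subject_id`, `n_flagged`,
#'   `multi_idp`) and `per_idp` (`idp`, `n_flagged`).
#' @export
outlier_frequency <- function(table) {
  if (!inherits(table, "outlier_table")) {
    abort("`table` must come from flag_outliers().")
  }
  per_subject <- table |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_flagged = sum(.data$flagged), .groups = "drop") |>
    dplyr::mutate(multi_idp = .data$n_flagged >= 2L)
  per_idp <- table |>
    dplyr::group_by(.data$idp) |>
    dplyr::summarise(n_flagged = sum(.data$flagged), .groups = "drop")
  list(per_subject = per_subject, per_idp = per_idp)
}

#' Attach review categories to flagged subjects
#'
#' Merges per-subject artefact-category labels (from human review or
#' synthetic truth) into the outlier table. Flagged subjects without a
#' label stay `"unreviewed"`; labels supplied for non-flagged subjects
#' are stored with a warning.
#'
#' @param table An `outlier_table`.
#' @param labels Tibble with columns `subject_id`, `category`.
#' @return The outlier table with its `category` column updated.
#' @export
assign_categories <- function(table, labels) {
  if (!inherits(table, "outlier_table")) {
    abort("`table` must come from flag_outliers().")
  }
  if (!all(c("subject_id", "category") %in% names(labels))) {
    abort("`labels` must have columns subject_id, category.")
  }
  flagged_ids <- unique(table$subject_id[table$flagged])
  stray <- setdiff(unique(labels$subject_id), flagged_ids)
  if (length(stray) > 0L) {
    warn(sprintf("%d label(s) refer to non-flagged subjects; stored anyway.",
                 length(stray)))
  }
  lab <- setNames(as.character(labels$category),
                  as.character(labels$subject_id))
  hit <- table$subject_id %in% names(lab)
  table$category[hit] <- unname(lab[table$subject_id[hit]])
  table$category[table$flagged & is.na(table$category)] <- "unreviewed"
  table
}
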