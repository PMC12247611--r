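# Prediction, deviation z-scores, centiles, fit statistics and
# refit-after-exclusion comparison for fitted normative models.

model_design <- function(model, ages) {
  nm_basis_matrix(model$basis, ages)
}

# predictive pieces on the warped scale: mean Phi'm, noise variance
# 1/beta, modelling-uncertainty variance phi' A^{-1} phi per row
warped_prediction <- function(model, ages) {
  Phi <- model_design(model, ages)
  mu <- drop(Phi %*% model$m)
  # sigma*^2 = rowwise quadratic form in A^{-1}
  V <- backsolve(model$chol_A, forwardsolve(t(model$chol_A), t(Phi)))
  sigma_star2 <- colSums(t(Phi) * V)
  list(mu = mu, sigma2 = 1 / model$beta,
       sigma_star2 = pmax(sigma_star2, 0))
}

#' Predict from a normative model
#'
#' Returns, per subject, the predicted mean on the original phenotype
#' scale (`y_hat`, the inverse-warped predictive median), the estimated
#' noise variance `sigma2` and the modelling-uncertainty variance
#' `sigma_star2` (both on the warped scale, the scale on which the
#' deviation z-score is defined).
#'
#' @param object A fitted `normative_model`.
#' @param newdata A data frame containing the age column used in
#'   fitting, or a numeric vector of ages.
#' @param ... Unused.
#' @return A tibble with columns `age`, `y_hat`, `sigma2`, `sigma_star2`.
#' @export
predict.normative_model <- function(object, newdata, ...) {
  ages <- if (is.numeric(newdata)) newdata else newdata[[object$age_col]]
  if (is.null(ages)) abort("`newdata` must contain the age column.")
  wp <- warped_prediction(object, ages)
  tibble(age = ages,
         y_hat = warp_inverse(wp$mu, object$warp),
         sigma2 = wp$sigma2,
         sigma_star2 = wp$sigma_star2)
}

#' Per-subject deviation z-scores
#'
#' The deviation score of subject n for phenotype d is
#' \deqn{z_{nd} = \frac{y_{nd} - \hat y_{nd}}{\sqrt{\sigma_d^2 + (\sigma^{*2})_d}}}
#' with the response and prediction taken on the warped (Gaussianised)
#' scale, where the residuals are as close to Gaussian as the warp can
#' make them, so the score is interpretable in standard deviations.
#'
#' @param model A fitted `normative_model`.
#' @param data Data frame with the age and phenotype columns used in
#'   fitting.
#' @return A tibble with `age`, `y`, `y_hat`, `sigma2`, `sigma_star2`, `z`.
#' @export
compute_zscores <- function(model, data) {
  ages <- data[[model$age_col]]
  y <- data[[model$idp]]
  if (is.null(ages) || is.null(y)) {
    abort("`data` must contain the model's age and phenotype columns.")
  }
  wp <- warped_prediction(model, ages)
  t_obs <- warp_forward(y, model$warp)
  z <- (t_obs - wp$mu) / sqrt(wp$sigma2 + wp$sigma_star2)
  tibble(age = ages, y = y,
         y_hat = warp_inverse(wp$mu, model$warp),
         sigma2 = wp$sigma2, sigma_star2 = wp$sigma_star2, z = z)
}

#' @rdname fit_normative
#' @param data Data frame to augment with predictions and z-scores.
#' @exportS3Method generics::augment
augment.normative_model <- function(x, data, ...) {
  zs <- compute_zscores(x, data)
  data$.fitted <- zs$y_hat
  data$.sigma2 <- zs$sigma2
  data$.sigma_star2 <- zs$sigma_star2
  data$.z <- zs$z
  as_tibble(data)
}

#' Centile curves on the original phenotype scale
#'
#' The q-th centile at age x is
#' `warp_inverse(Phi(x)'m + Phi_q * sqrt(sigma2 + sigma_star2))` with
#' `Phi_q` the standard normal quantile; the warp is monotone, so the
#' 50th centile is exactly the inverse-warped predictive mean and
#' centiles never cross.
#'
#' @param model A fitted `normative_model`.
#' @param ages Numeric vector of ages at which to evaluate the curves.
#' @param levels Centile levels in percent, strictly inside (0, 100).
#' @return A tibble with columns `age`, `level`, `value`.
#' @export
compute_centiles <- function(model, ages,
                             levels = c(1, 5, 25, 50, 75, 95, 99)) {
  if (any(levels <= 0 | levels >= 100)) {
    abort("Centile `levels` must lie strictly between 0 and 100.")
  }
  wp <- warped_prediction(model, ages)
  s <- sqrt(wp$sigma2 + wp$sigma_star2)
  out <- lapply(levels, function(q) {
    tibble(age = ages, level = q,
           value = warp_inverse(wp$mu + qnorm(q / 100) * s, model$warp))
  })
  dplyr::bind_rows(out)
}

#' Fit statistics of a normative model on held-out data
#'
#' Explained variance is computed on the original phenotype scale,
#' `EV = 1 - var(y - y_hat) / var(y)` with `y_hat` the inverse-warped
#' predictive median; skew and kurtosis are the Fisher skewness and
#' excess kurtosis of the deviation z-scores (near 0 when the warp has
#' Gaussianised the residuals).
#'
#' @param model A fitted `normative_model`.
#' @param data Held-out data frame with the age and phenotype columns.
#' @return A one-row tibble: `idp`, `n`, `explained_variance`, `skew`,
#'   `kurtosis`.
#' @export
fit_statistics <- function(model, data) {
  if (nrow(data) == 0L) abort("Held-out data must be non-empty.")
  zs <- compute_zscores(model, data)
  vy <- var(zs$y)
  if (!is.finite(vy) || vy == 0) {
    abort("Held-out response has zero variance; explained variance undefined.")
  }
  tibble(idp = model$idp %||% NA_character_,
         n = nrow(zs),
         explained_variance = 1 - var(zs$y - zs$y_hat) / vy,
         skew = sample_skewness(zs$z),
         kurtosis = sample_excess_kurtosis(zs$z))
}

#' Refit after outlier exclusion and compare z-scores
#'
#' Refits the model on the non-excluded subjects (same configuration and
#' optimiser seeds), recomputes the deviation z-scores of the retained
#' subjects under both the original and refitted model, and returns the
#' two-sided paired t-test of the change. When the refit leaves every
#' retained z-score unchanged (e.g. an empty exclusion mask) the t-test
#' is degenerate and the p-value is the sentinel `NA` with
#' `degenerate = TRUE`.
#'
#' @param model A fitted `normative_model`.
#' @param data The data frame the model was fitted to.
#' @param exclude Logical vector (length `nrow(data)`) marking subjects
#'   to exclude from the refit; must exclude fewer than 50%.
#' @return A list of class `nm_refit`: `refit` (the refitted model),
#'   `statistic`, `p_value`, `n_retained`, `degenerate`, and the two
#'   z-score vectors.
#' @export
refit_compare <- function(model, data, exclude) {
  if (!is.logical(exclude) || length(exclude) != nrow(data)) {
    abort("`exclude` must be a logical vector with one entry per row of `data`.")
  }
  if (mean(exclude) >= 0.5) {
    abort("`exclude` must drop fewer than 50% of subjects.")
  }
  kept <- data[!exclude, , drop = FALSE]
  refit <- fit_normative_impl(kept[[model$age_col]], kept[[model$idp]],
                              warp_type = model$warp_type,
                              standardize = model$standardize %||% "fixed",
                              n_restarts = model$n_restarts,
                              seed = model$seed,
                              n_knots = length(model$basis$knots))
  refit$idp <- model$idp
  refit$age_col <- model$age_col
  z_before <- compute_zscores(model, kept)$z
  z_after <- compute_zscores(refit, kept)$z
  d <- z_after - z_before
  degenerate <- sd(d) == 0 || !is.finite(sd(d))
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_
  } else {
    tt <- t.test(z_after, z_before, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(refit = refit, statistic = stat, p_value = p,
                 n_retained = nrow(kept), degenerate = degenerate,
                 z_before = z_before, z_after = z_after),
            class = "nm_refit")
}

#' @export
print.nm_refit <- function(x, ...) {
  cat(sprintf("<nm_refit> n retained = %d; paired t-test ", x$n_retained))
  if (x$degenerate) cat("degenerate (z-scores unchanged)\n")
  else cat(sprintf("t = %.3f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}
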