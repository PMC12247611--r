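# Independent oracles and small fixture builders used across the suite.

# Cox-de Boor recursion, written independently of splines::bs: evaluates
# the i-th B-spline of order k (degree k-1) on knot vector kv.
deboor_basis <- function(x, knots, degree) {
  # clamped knot vector
  kv <- c(rep(knots[1], degree), knots, rep(knots[length(knots)], degree))
  n_fun <- length(kv) - degree - 1L
  B <- function(i, k, x) {
    if (k == 0) {
      # half-open intervals, closed at the right end of the domain
      hi <- kv[i + 1]
      lo <- kv[i]
      if (hi == kv[length(kv)] && x == hi) return(as.numeric(lo < x))
      return(as.numeric(lo <= x & x < hi))
    }
    d1 <- kv[i + k] - kv[i]
    d2 <- kv[i + k + 1] - kv[i + 1]
    t1 <- if (d1 > 0) (x - kv[i]) / d1 * B(i, k - 1, x) else 0
    t2 <- if (d2 > 0) (kv[i + k + 1] - x) / d2 * B(i + 1, k - 1, x) else 0
    t1 + t2
  }
  vapply(seq_len(n_fun), function(i) B(i, degree, x), numeric(1))
}

# ICC(3,k) via R's ANOVA machinery (two-way, subjects + raters), as an
# independent route to the mean squares.
icc3k_aov_oracle <- function(ratings) {
  x <- as.matrix(ratings)
  d <- data.frame(score = as.vector(x),
                  subject = factor(rep(seq_len(nrow(x)), ncol(x))),
                  rater = factor(rep(seq_len(ncol(x)), each = nrow(x))))
  tab <- anova(stats::aov(score ~ subject + rater, data = d))
  ms_rows <- tab["subject", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  (ms_rows - ms_err) / ms_rows
}

# Brute-force PR curve: loop over every distinct cut-point and count.
pr_oracle <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  cuts <- sort(unique(scores), decreasing = TRUE)
  P <- sum(truth)
  prec <- rec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred <- scores >= cuts[i]
    tp <- sum(pred & truth == 1L)
    prec[i] <- tp / sum(pred)
    rec[i] <- tp / P
  }
  auc <- sum(diff(c(0, rec)) * prec)
  list(cutoff = cuts, precision = prec, recall = rec, auc = auc)
}

# model-family data: warped-scale spline trend plus Gaussian noise put
# through the inverse sinh-arcsinh warp (a0 = 0, b0 = 1 unless given)
make_warped_data <- function(n, epsilon = 0.5, delta = 1.3, a0 = 0, b0 = 1,
                             noise = 1, seed = 1) {
  withr::with_seed(seed, {
    age <- runif(n, 45, 85)
    trend <- 0.5 - 0.03 * (age - 65) + 0.0005 * (age - 65)^2
    t <- trend + rnorm(n, 0, noise)
    tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = age,
      y = warp_inverse(t, warp_params(epsilon, delta, a0, b0)))
  })
}

make_linear_gaussian_data <- function(n, seed = 1, sigma = 0.5) {
  withr::with_seed(seed, {
    age <- runif(n, 45, 85)
    tibble::tibble(age = age,
                   y = 2 + 0.05 * age + rnorm(n, 0, sigma))
  })
}
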