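test_that("a single spike among constant-free columns is the only flag", {
  withr::with_seed(61, {
    q <- tibble::tibble(subject_id = sprintf("S%02d", 1:40),
                        a = rnorm(40, 0, 1), b = rnorm(40, 5, 2))
  })
  q$a[7] <- mean(q$a) + 10 * sd(q$a)
  freq <- qqc_outlier_frequency(q, threshold_sd = 3)
  expect_gte(freq$n_flagged[7], 1)
  flags <- attr(freq, "flags")
  expect_true(flags[7, "a"])
})

test_that("flag counts match an exhaustive per-cell loop", {
  withr::with_seed(62, {
    q <- tibble::tibble(a = rnorm(100), b = rt(100, 3), c = rexp(100))
  })
  freq <- qqc_outlier_frequency(q, threshold_sd = 2)
  manual <- integer(100)
  for (i in 1:100) {
    for (col in c("a", "b", "c")) {
      v <- q[[col]]
      if (abs(v[i] - mean(v)) > 2 * sd(v)) manual[i] <- manual[i] + 1L
    }
  }
  expect_identical(freq$n_flagged, manual)
})

test_that("zero-variance descriptors are excluded with a warning", {
  q <- tibble::tibble(a = rnorm(30), dead = rep(1, 30))
  expect_warning(freq <- qqc_outlier_frequency(q), "dead")
  expect_false("dead" %in% colnames(attr(freq, "flags")))
})

test_that("correlation matrix is symmetric with unit diagonal and exact
           anticorrelation", {
  withr::with_seed(63, x <- rnorm(50))
  m <- qc_correlation_matrix(tibble::tibble(x = x, y = -x, z = rnorm(50)))
  expect_equal(m["x", "y"], -1, tolerance = 1e-12)
  expect_equal(diag(m), setNames(rep(1, 3), c("x", "y", "z")))
  expect_equal(m, t(m))
})

test_that("correlations match the textbook Pearson formula and the
           matrix is positive semi-definite", {
  withr::with_seed(64, {
    d <- tibble::tibble(a = rnorm(80), b = rnorm(80), c = rnorm(80),
                        d = rnorm(80), e = rnorm(80), f = rnorm(80))
  })
  d$b <- d$a * 0.5 + d$b
  m <- qc_correlation_matrix(d)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in names(d)) for (j in names(d)) {
    expect_equal(m[i, j], pearson(d[[i]], d[[j]]), tolerance = 1e-12)
  }
  expect_gte(min(eigen(m, symmetric = TRUE)$values), -1e-10)
})

test_that("zero-variance measures yield the NA sentinel", {
  d <- tibble::tibble(a = rnorm(10), flat = rep(2, 10))
  expect_warning(m <- qc_correlation_matrix(d), "flat")
  expect_true(is.na(m["a", "flat"]))
  expect_identical(m["flat", "flat"], 1)
  expect_error(qc_correlation_matrix(d[1:2, ]), "3 rows")
})
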