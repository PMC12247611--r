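test_that("a feature identical to the label is classified perfectly", {
  withr::with_seed(51, {
    y <- c(rep(3, 30), sample(1:2, 170, TRUE))
    feats <- tibble::tibble(marker = as.numeric(y == 3),
                            noise = rnorm(200))
  })
  ev <- balanced_svm_evaluation(feats, y, n_subsamples = 5, seed = 1)
  expect_equal(ev$per_subsample$accuracy, rep(1, 5))
  expect_equal(ev$per_subsample$sensitivity, rep(1, 5))
  expect_equal(ev$per_subsample$specificity, rep(1, 5))
})

test_that("evaluation is deterministic given the seed and balanced per
           subsample", {
  withr::with_seed(52, {
    y <- c(rep(3, 25), rep(1, 175))
    feats <- tibble::tibble(a = rnorm(200), b = rnorm(200))
  })
  e1 <- balanced_svm_evaluation(feats, y, n_subsamples = 4, seed = 9)
  e2 <- balanced_svm_evaluation(feats, y, n_subsamples = 4, seed = 9)
  expect_identical(e1$per_subsample, e2$per_subsample)
  expect_named(e1$summary, c("metric", "mean", "sd"))
})

test_that("degenerate label sets are refused", {
  feats <- tibble::tibble(a = rnorm(20))
  expect_error(balanced_svm_evaluation(feats, rep(1, 20)), "Both classes")
  expect_error(balanced_svm_evaluation(feats, rep(4, 20)), "scores")
  expect_error(balanced_svm_evaluation(feats, c(rep(3, 10), rep(1, 5))),
               "one entry per")
})

test_that("cross-validated decision values rank a separable positive
           class on top", {
  withr::with_seed(53, {
    y <- c(rep(3, 25), rep(1, 175))
    feats <- tibble::tibble(a = rnorm(200) + 6 * (y == 3),
                            b = rnorm(200))
  })
  dec <- svm_decision_values(feats, y, seed = 2)
  expect_equal(pr_auc(dec, y == 3), 1, tolerance = 0.02)
})
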