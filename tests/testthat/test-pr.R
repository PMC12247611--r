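test_that("perfect ranking yields unit area", {
  truth <- c(rep(1, 5), rep(0, 20))
  scores <- c(runif(5, 0.8, 1), runif(20, 0, 0.5))
  expect_equal(pr_auc(scores, truth), 1, tolerance = 1e-12)
})

test_that("the six-point worked example matches the brute-force oracle", {
  truth <- c(1, 1, 0, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  cv <- pr_curve(scores, truth)
  oracle <- pr_oracle(scores, truth)
  expect_equal(cv$cutoff, oracle$cutoff)
  expect_equal(cv$precision, oracle$precision, tolerance = 1e-12)
  expect_equal(cv$recall, oracle$recall, tolerance = 1e-12)
  expect_equal(attr(cv, "auc"), oracle$auc, tolerance = 1e-12)
})

test_that("tied scores are grouped at a single cut-point and random
           curves match the oracle", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- 40
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      truth <- rbinom(n, 1, 0.3)
      if (sum(truth) == 0) truth[1] <- 1
      cv <- pr_curve(scores, truth)
      oracle <- pr_oracle(scores, truth)
      expect_equal(nrow(cv), length(unique(scores)))
      expect_equal(cv$precision, oracle$precision, tolerance = 1e-12)
      expect_equal(attr(cv, "auc"), oracle$auc, tolerance = 1e-12)
      expect_true(all(diff(cv$recall) >= 0))
      expect_gte(attr(cv, "auc"), 0)
      expect_lte(attr(cv, "auc"), 1)
    }
  })
})

test_that("threshold sweep evaluates binary operating points plus the
           continuous rankings", {
  withr::with_seed(42, {
    z <- c(runif(180, 0, 5), runif(20, 8, 15))
    truth <- c(rep(0, 180), rep(1, 20))
  })
  sw <- pr_threshold_sweep(z, truth, thresholds = c(3, 5, 7),
                           svm_scores = rev(seq_along(z)) / 200)
  expect_equal(nrow(sw), 5)
  expect_true(all(c("nm_z_gt_3", "nm_z_gt_7", "nm_max_abs_z", "svm") %in%
                    sw$method))
  # all positives above 7, all negatives below 5: those rules are perfect
  expect_equal(sw$auc[sw$method == "nm_z_gt_7"], 1, tolerance = 1e-12)
  expect_equal(sw$auc[sw$method == "nm_max_abs_z"], 1, tolerance = 1e-12)
})

test_that("degenerate inputs are refused", {
  expect_error(pr_curve(c(1, 2), c(0, 0)), "positive")
  expect_error(pr_curve(c(1, NA), c(0, 1)), "finite")
  expect_error(pr_threshold_sweep(1:3, c(0, 1, 1), thresholds = c(-1)),
               "positive")
})
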