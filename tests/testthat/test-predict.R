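fit_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_warped_data(800, seed = 8)
      cache <<- list(data = d, model = fit_normative(d, y, seed = 1))
    }
    cache
  }
})

test_that("modelling-uncertainty variance is non-negative and grows toward
           the support boundary", {
  fx <- fit_fixture()
  p <- predict(fx$model, seq(45, 85, length.out = 41))
  expect_true(all(p$sigma_star2 >= 0))
  centre <- p$sigma_star2[which.min(abs(p$age - 65))]
  expect_gt(p$sigma_star2[1], centre)
  expect_gt(p$sigma_star2[nrow(p)], centre)
})

test_that("a prior-dominated posterior shrinks the warped mean to zero", {
  fx <- fit_fixture()
  Phi <- nm_basis_matrix(fx$model$basis, fx$data$age)
  pre <- list(Phi = Phi, PtP = crossprod(Phi))
  post <- normqc:::nm_posterior(c(log(1e12), log(1), 0, 0), fx$data$y,
                                pre, "none")
  expect_lt(max(abs(post$m)), 1e-6)
})

test_that("z-scores follow the deviation formula on the warped scale", {
  fx <- fit_fixture()
  zs <- compute_zscores(fx$model, fx$data)
  # manual recomputation from model internals
  Phi <- nm_basis_matrix(fx$model$basis, fx$data$age)
  mu <- drop(Phi %*% fx$model$m)
  s2 <- 1 / fx$model$beta
  ss2 <- rowSums((Phi %*% solve(fx$model$A)) * Phi)
  z_ref <- (warp_forward(fx$data$y, fx$model$warp) - mu) / sqrt(s2 + ss2)
  expect_equal(zs$z, z_ref, tolerance = 1e-8)
  # pure arithmetic: residual 4 with sigma2 3 and sigma_star2 1 gives 2
  expect_identical(4 / sqrt(3 + 1), 2)
})

test_that("median centile equals the inverse-warped mean and centiles
           never cross", {
  fx <- fit_fixture()
  grid <- seq(45, 85, length.out = 31)
  cent <- compute_centiles(fx$model, grid, levels = c(1, 25, 50, 75, 99))
  p <- predict(fx$model, grid)
  med <- cent$value[cent$level == 50]
  expect_equal(med, p$y_hat, tolerance = 1e-12)
  wide <- tidyr::pivot_wider(cent, names_from = "level",
                             values_from = "value")
  expect_true(all(wide$`1` < wide$`25` & wide$`25` < wide$`50` &
                    wide$`50` < wide$`75` & wide$`75` < wide$`99`))
  expect_error(compute_centiles(fx$model, grid, levels = c(0, 50)),
               "between 0 and 100")
})

test_that("fit statistics: perfect median-curve data give EV of one and
           moments match an independent oracle", {
  fx <- fit_fixture()
  d <- fx$data
  d$y <- predict(fx$model, d)$y_hat
  fs <- fit_statistics(fx$model, d)
  expect_equal(fs$explained_variance, 1, tolerance = 1e-9)
  x <- c(2.1, -0.4, 0.9, 3.3, -1.7, 0.2, 1.1, -2.5, 0.6, 0.0)
  expect_equal(normqc:::sample_skewness(x),
               unname(e1071::skewness(x, type = 1)), tolerance = 1e-12)
  expect_equal(normqc:::sample_excess_kurtosis(x),
               unname(e1071::kurtosis(x, type = 1)), tolerance = 1e-12)
  expect_error(fit_statistics(fx$model, d[0, ]), "non-empty")
})

test_that("refit after an empty exclusion mask is a degenerate no-op", {
  fx <- fit_fixture()
  rc <- refit_compare(fx$model, fx$data, rep(FALSE, nrow(fx$data)))
  expect_true(rc$degenerate)
  expect_identical(rc$p_value, NA_real_)
  expect_equal(rc$z_before, rc$z_after, tolerance = 1e-12)
  expect_error(refit_compare(fx$model, fx$data,
                             rep(TRUE, nrow(fx$data))), "50%")
})

test_that("excluding heavy contamination improves the refit on clean
           held-out subjects", {
  art <- artefact_spec("acquisition", prevalence = 0.02,
                       affected_idps = "MD_fornix", shift_sd = 10)
  spec <- cohort_spec(1500, idp_names = "MD_fornix",
                      contamination = list(art), seed = 9)
  co <- simulate_cohort(spec, raters = FALSE, qqc = FALSE)
  train <- co[1:1000, ]; test <- co[1001:1500, ]
  m <- fit_normative(train, MD_fornix, seed = 1)
  rc <- refit_compare(m, train, train$true_category != "clean")
  clean_test <- test[test$true_category == "clean", ]
  ev0 <- fit_statistics(m, clean_test)$explained_variance
  ev1 <- fit_statistics(rc$refit, clean_test)$explained_variance
  expect_gte(ev1, ev0)
  expect_false(rc$degenerate)
  expect_lte(rc$p_value, 1)
})
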