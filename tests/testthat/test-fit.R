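test_that("identity-warp fit reproduces the conjugate posterior", {
  d <- make_linear_gaussian_data(300, seed = 4)
  m <- fit_normative(d, y, warp = "identity", seed = 1)
  Phi <- nm_basis_matrix(m$basis, d$age)
  A_ref <- m$alpha * diag(ncol(Phi)) + m$beta * crossprod(Phi)
  m_ref <- m$beta * solve(A_ref, crossprod(Phi, d$y))
  expect_equal(m$A, A_ref, tolerance = 1e-8)
  expect_equal(m$m, drop(m_ref), tolerance = 1e-8)
})

test_that("fitting is deterministic given data and seed", {
  d <- make_warped_data(400, seed = 5)
  m1 <- fit_normative(d, y, seed = 3)
  m2 <- fit_normative(d, y, seed = 3)
  expect_identical(glance(m1), glance(m2))
  expect_identical(m1$m, m2$m)
})

test_that("degenerate and undersized inputs are refused", {
  d <- tibble::tibble(age = runif(50, 45, 85), y = 1)
  expect_error(fit_normative(d, y), "constant")
  d2 <- make_warped_data(6, seed = 1)
  expect_error(fit_normative(d2, y), "at least")
  expect_error(fit_normative(d2, nope), "not found")
})

test_that("tidy and glance expose the posterior and hyperparameters", {
  d <- make_warped_data(300, seed = 6)
  m <- fit_normative(d, y, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), m$basis$n_fun)
  expect_true(all(td$std.error > 0))
  gl <- glance(m)
  expect_named(gl, c("n", "n_basis", "alpha", "beta", "epsilon", "delta",
                     "a0", "b0", "nll", "converged"))
  expect_gt(gl$beta, 0)
  expect_gt(gl$delta, 0)
})

test_that("fixed standardisation pins the warp affine at training moments", {
  d <- make_warped_data(300, a0 = 0.5, b0 = 0.03, seed = 7)
  m <- fit_normative(d, y, standardize = "fixed", seed = 1)
  expect_equal(m$warp$a0, mean(d$y), tolerance = 1e-12)
  expect_equal(m$warp$b0, sd(d$y), tolerance = 1e-12)
  m0 <- fit_normative(d, y, standardize = "none", seed = 1)
  expect_identical(m0$warp$a0, 0)
  expect_identical(m0$warp$b0, 1)
})

test_that("fit_normative_set maps over phenotypes and keeps diagnostics", {
  spec <- cohort_spec(150, idp_names = c("FA_fornix", "MD_fornix"), seed = 2)
  co <- simulate_cohort(spec, raters = FALSE, qqc = FALSE)
  fits <- fit_normative_set(co, idps = c("FA_fornix", "MD_fornix"), seed = 1)
  expect_equal(fits$idp, c("FA_fornix", "MD_fornix"))
  expect_s3_class(fits$model[[1]], "normative_model")
  zt <- zscore_table(fits, co)
  expect_equal(nrow(zt), 300)
  expect_true(all(is.finite(zt$z)))
})
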