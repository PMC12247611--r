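test_that("dimension contract: clean cohort has one row per subject and
           all 24 phenotype columns", {
  spec <- cohort_spec(100, seed = 1)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co), 100)
  expect_true(all(default_idp_names() %in% names(co)))
  expect_true(all(co$true_category == "clean"))
  expect_true(all(c("rater1", "rater2") %in% names(co)))
})

test_that("ages stay inside the configured range", {
  co <- simulate_cohort(cohort_spec(500, age_range = c(45, 85), seed = 2),
                        raters = FALSE, qqc = FALSE)
  expect_gte(min(co$age), 45)
  expect_lte(max(co$age), 85)
})

test_that("realised contamination count is binomially consistent", {
  art <- artefact_spec("processing", prevalence = 0.02,
                       affected_idps = "MD_fornix")
  spec <- cohort_spec(10000, idp_names = "MD_fornix",
                      contamination = list(art), seed = 3)
  co <- simulate_cohort(spec, raters = FALSE, qqc = FALSE)
  n_bad <- sum(co$true_category == "processing")
  expect_lt(abs(n_bad - 200), 3 * sqrt(10000 * 0.02 * 0.98))
})

test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(200, contamination = default_artefact_specs(),
                      seed = 7)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
})

test_that("clean residuals are Gaussian after the true forward warp", {
  nm <- "ISOVF_fornix"
  spec <- cohort_spec(2000, idp_names = nm, seed = 5)
  co <- simulate_cohort(spec, raters = FALSE, qqc = FALSE)
  p <- spec$idp_params[1, ]
  w <- warp_params(p$epsilon, p$delta, p$a0, p$b0)
  tr <- normqc:::trend_fun(p$trend[[1]], spec$age_range)
  resid <- warp_forward(co[[nm]], w) - tr(co$age)
  ks <- stats::ks.test(resid, "pnorm", mean = 0, sd = p$noise_scale)
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid cohort specs are refused naming the offending field", {
  expect_error(cohort_spec(0), "n_subjects")
  expect_error(cohort_spec(10, age_range = c(85, 45)), "age_range")
  expect_error(artefact_spec("processing", prevalence = 0.5,
                             affected_idps = "x"), "prevalence")
  expect_error(cohort_spec(10, rater_reliability = 1.5),
               "rater_reliability")
  bad <- artefact_spec("incidental", prevalence = 0.01,
                       affected_idps = "no_such_idp")
  expect_error(cohort_spec(10, contamination = list(bad)), "unknown")
})

test_that("perfectly reliable raters reproduce the truth; scores always
           stay on the 1-3 scale", {
  truth <- sample(c(1, 2, 3), 300, replace = TRUE)
  r <- simulate_rater_scores(truth, reliability = 1, seed = 1)
  expect_identical(r$rater1, as.integer(truth))
  expect_identical(r$rater2, as.integer(truth))
  r0 <- simulate_rater_scores(truth, reliability = 0.2, seed = 2)
  expect_true(all(unlist(r0) %in% 1:3))
  expect_error(simulate_rater_scores(truth, reliability = 1.2),
               "reliability")
  expect_error(simulate_rater_scores(c(0, 1), reliability = 1), "severities")
})

test_that("quality-descriptor table has 21 columns with the configured
           baselines and a null effect size changes nothing", {
  spec <- cohort_spec(4000, idp_names = "FA_fornix",
                      contamination = list(
                        artefact_spec("acquisition", 0.05, "FA_fornix")),
                      seed = 6)
  co <- simulate_cohort(spec, raters = FALSE, qqc = FALSE)
  q <- simulate_qqc(co, effect_size = 1, seed = 3)
  expect_equal(ncol(q), 21)
  defs <- normqc:::qqc_descriptor_defaults()
  clean <- co$true_category == "clean"
  for (i in c(1, 12, 17)) { # motion, SNR, T1 discrepancy
    se <- defs$sd[i] / sqrt(sum(clean))
    expect_lt(abs(mean(q[[defs$name[i]]][clean]) - defs$mean[i]), 5 * se)
  }
  # acquisition artefacts lower SNR and raise motion when effect size > 0
  expect_lt(mean(q$snr_b0[!clean]), mean(q$snr_b0[clean]))
  expect_gt(mean(q$avg_abs_motion[!clean]), mean(q$avg_abs_motion[clean]))
  # effect size 0: contaminated column indistinguishable from clean
  q0 <- simulate_qqc(co, effect_size = 0, seed = 4)
  ks <- stats::ks.test(q0$snr_b0[clean], q0$snr_b0[!clean])
  expect_gt(ks$p.value, 0.01)
})
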