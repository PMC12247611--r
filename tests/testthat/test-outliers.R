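z_fixture <- function(z_values, idp = "FA_fornix") {
  tibble::tibble(subject_id = sprintf("S%03d", seq_along(z_values)),
                 idp = idp, z = z_values)
}

test_that("the 7-SD rule is strict and two-sided at the boundary", {
  ot <- flag_outliers(z_fixture(c(7.01, -7.5, 6.99, 7.0, -7.0)), 7)
  expect_identical(ot$flagged, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  one_sided <- flag_outliers(z_fixture(c(7.5, -7.5)), 7, two_sided = FALSE)
  expect_identical(one_sided$flagged, c(TRUE, FALSE))
})

test_that("a quiet cohort yields no outliers and empty unique set", {
  ot <- flag_outliers(z_fixture(runif(50, -3, 3)), 7)
  expect_identical(sum(ot$flagged), 0L)
  freq <- outlier_frequency(ot)
  expect_true(all(freq$per_subject$n_flagged == 0))
  expect_true(all(!freq$per_subject$multi_idp))
})

test_that("non-finite z-scores are refused naming the offender", {
  z <- z_fixture(c(1, NaN, 2))
  expect_error(flag_outliers(z, 7), "S002")
})

test_that("frequency marginals match a brute-force double loop", {
  withr::with_seed(21, {
    ids <- sprintf("S%03d", 1:40)
    z <- expand.grid(subject_id = ids,
                     idp = paste0("idp", 1:6),
                     stringsAsFactors = FALSE)
    z$z <- rnorm(nrow(z), 0, 5)
    ot <- flag_outliers(tibble::as_tibble(z), threshold = 4)
    freq <- outlier_frequency(ot)
    for (s in ids) {
      manual <- 0
      for (k in paste0("idp", 1:6)) {
        manual <- manual + (abs(z$z[z$subject_id == s & z$idp == k]) > 4)
      }
      expect_identical(
        freq$per_subject$n_flagged[freq$per_subject$subject_id == s],
        as.integer(manual))
    }
    per_idp_manual <- tapply(abs(z$z) > 4, z$idp, sum)
    expect_identical(freq$per_idp$n_flagged[order(freq$per_idp$idp)],
                     as.integer(per_idp_manual[sort(names(per_idp_manual))]))
  })
})

test_that("flag sets are nested across a threshold grid", {
  withr::with_seed(22, z <- z_fixture(rnorm(500, 0, 4)))
  sets <- lapply(c(3, 4, 5, 6, 7), function(t) {
    which(flag_outliers(z, t)$flagged)
  })
  for (i in 2:5) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("category labels merge onto flagged subjects only", {
  ot <- flag_outliers(z_fixture(c(9, 1, -8, 2)), 7)
  labs <- tibble::tibble(subject_id = "S001", category = "acquisition")
  ot2 <- assign_categories(ot, labs)
  expect_identical(ot2$category, c("acquisition", NA, "unreviewed", NA))
  stray <- tibble::tibble(subject_id = "S002", category = "processing")
  expect_warning(ot3 <- assign_categories(ot, stray), "non-flagged")
  expect_identical(ot3$category[2], "processing")
})
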