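# Synthetic cohort generator: age-dependent, non-Gaussian phenotypes
# with rare multi-class artefact contamination, simulated raters and a
# quantitative-QC descriptor table. The clean generative law is the
# fitted model family itself: a smooth age trend on the warped
# (Gaussianised) scale plus Gaussian noise, mapped back through the
# inverse sinh-arcsinh warp — so parameter recovery, calibration and
# centile coverage are meaningful checks with a known truth.

#' Default diffusion phenotype names
#'
#' The default panel of 24 imaging-derived phenotypes: four diffusion
#' metrics (FA, MD from the tensor model; ICVF, ISOVF from NODDI)
#' crossed with six white-matter tracts (corpus callosum, corticospinal
#' tract L/R, uncinate fasciculus L/R, fornix).
#'
#' @return Character vector of 24 phenotype names, `metric_tract`.
#' @export
default_idp_names <- function() {
  metrics <- c("FA", "MD", "ICVF", "ISOVF")
  tracts <- c("corpus_callosum", "corticospinal_tract_L",
              "corticospinal_tract_R", "uncinate_fasciculus_L",
              "uncinate_fasciculus_R", "fornix")
  as.vector(t(outer(metrics, tracts, paste, sep = "_")))
}

idp_metric <- function(idp_names) sub("_.*$", "", idp_names)
idp_tract <- function(idp_names) sub("^[^_]+_", "", idp_names)

# Per-metric generative defaults: location/scale of the phenotype
# (MD in units of 1e-3 mm^2/s), skew/tail of the warp, and the age
# trend as five control values on the warped scale (anchored at evenly
# spaced ages). FA and ICVF decline with age, MD and ISOVF rise; the
# fornix gets an inflated scale to mimic its large measurement variance.
default_idp_params <- function(idp_names) {
  base <- list(
    FA    = list(a0 = 0.50, b0 = 0.025, epsilon = 0.25, delta = 0.90,
                 trend = c(0.50, 0.28, 0.00, -0.35, -0.80)),
    MD    = list(a0 = 0.80, b0 = 0.040, epsilon = 0.35, delta = 0.90,
                 trend = c(-0.60, -0.30, 0.00, 0.40, 0.90)),
    ICVF  = list(a0 = 0.55, b0 = 0.030, epsilon = 0.30, delta = 0.90,
                 trend = c(0.50, 0.25, 0.00, -0.30, -0.70)),
    ISOVF = list(a0 = 0.15, b0 = 0.030, epsilon = 0.50, delta = 0.85,
                 trend = c(-0.50, -0.25, 0.00, 0.35, 0.80)))
  rows <- lapply(idp_names, function(nm) {
    met <- idp_metric(nm)
    p <- base[[met]]
    if (is.null(p)) p <- list(a0 = 0, b0 = 1, epsilon = 0.3, delta = 0.9,
                              trend = c(0.4, 0.2, 0, -0.2, -0.4))
    if (idp_tract(nm) == "fornix") p$b0 <- p$b0 * 2.5
    tibble(idp = nm, a0 = p$a0, b0 = p$b0, epsilon = p$epsilon,
           delta = p$delta, noise_scale = 1, trend = list(p$trend))
  })
  dplyr::bind_rows(rows)
}

#' Artefact contamination specification
#'
#' Describes one rare contamination class: its category, prevalence,
#' the phenotypes it displaces, the displacement magnitude in clean
#' residual SDs on the deviation scale (the warped residual scale on
#' which z-scores are measured; any sign), and the ground-truth visual
#' severity a perfect rater would assign. Displacing on the deviation
#' scale keeps the magnitude interpretable against a z threshold: a
#' 10-SD displacement sits near z = 10 under a clean reference model.
#'
#' @param category `"acquisition"`, `"processing"` or `"incidental"`.
#' @param prevalence Fraction of subjects affected, in `[0, 0.1)` — the
#'   rare-event regime the outlier rule targets.
#' @param affected_idps Character vector of affected phenotype names.
#' @param shift_sd Displacement of affected values, in clean residual
#'   SDs on the deviation scale (default 10, large enough for a 7-SD
#'   rule to see).
#' @param severity_score Ground-truth severity in `{2, 3}`.
#' @return An object of class `artefact_spec`.
#' @export
artefact_spec <- function(category = c("acquisition", "processing",
                                       "incidental"),
                          prevalence, affected_idps, shift_sd = 10,
                          severity_score = 3) {
  category <- match.arg(category)
  check_number(prevalence, "prevalence", lower = 0)
  if (prevalence >= 0.1) {
    abort("`prevalence` must be below 0.1 (rare-event regime).")
  }
  if (!is.character(affected_idps) || length(affected_idps) == 0L) {
    abort("`affected_idps` must be a non-empty character vector.")
  }
  check_number(shift_sd, "shift_sd")
  if (!severity_score %in% c(2, 3)) {
    abort("`severity_score` must be 2 or 3.")
  }
  structure(list(category = category, prevalence = prevalence,
                 affected_idps = affected_idps, shift_sd = shift_sd,
                 severity_score = severity_score),
            class = "artefact_spec")
}

#' Default three-class contamination
#'
#' Acquisition artefacts (e.g. truncated field of view, signal dropout)
#' corrupt every phenotype; processing errors (misregistration, brain
#' extraction failures) preferentially displace MD and ISOVF; incidental
#' findings displace a single structure (all metrics of the corpus
#' callosum). Total prevalence ~1.6%.
#'
#' @param idp_names Phenotype names the specs refer to.
#' @return List of three [artefact_spec()] objects.
#' @export
default_artefact_specs <- function(idp_names = default_idp_names()) {
  met <- idp_metric(idp_names)
  list(
    artefact_spec("acquisition", prevalence = 0.006,
                  affected_idps = idp_names, shift_sd = 10,
                  severity_score = 3),
    artefact_spec("processing", prevalence = 0.006,
                  affected_idps = idp_names[met %in% c("MD", "ISOVF")],
                  shift_sd = 10, severity_score = 2),
    artefact_spec("incidental", prevalence = 0.004,
                  affected_idps = idp_names[idp_tract(idp_names) ==
                                              "corpus_callosum"],
                  shift_sd = 10, severity_score = 2))
}

#' Cohort simulation specification
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param age_range Age range in years, default `c(45, 85)`.
#' @param idp_names Phenotype names (default the 24-phenotype panel).
#' @param idp_params Optional tibble of per-phenotype generative
#'   parameters (`idp`, `a0`, `b0`, `epsilon`, `delta`, `noise_scale`,
#'   `trend` list-column of warped-scale control values); defaults from
#'   [default_idp_params()].
#' @param contamination List of [artefact_spec()]s; prevalences must sum
#'   below 1. Default: none.
#' @param rater_reliability Probability each simulated rater reports the
#'   true severity, in `[0, 1]`.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, age_range = c(45, 85),
                        idp_names = default_idp_names(),
                        idp_params = NULL, contamination = list(),
                        rater_reliability = 0.9, seed = 1) {
  check_number(n_subjects, "n_subjects", lower = 1)
  if (length(age_range) != 2L || !all(is.finite(age_range)) ||
      age_range[1] >= age_range[2]) {
    abort("`age_range` must be (min, max) with min < max.")
  }
  if (!is.character(idp_names) || length(idp_names) == 0L ||
      anyDuplicated(idp_names) > 0L) {
    abort("`idp_names` must be unique non-empty names.")
  }
  if (is.null(idp_params)) idp_params <- default_idp_params(idp_names)
  req <- c("idp", "a0", "b0", "epsilon", "delta", "noise_scale", "trend")
  if (!all(req %in% names(idp_params)) ||
      !setequal(idp_params$idp, idp_names)) {
    abort("`idp_params` must describe exactly the phenotypes in `idp_names`.")
  }
  if (any(idp_params$noise_scale <= 0)) {
    abort("`noise_scale` must be positive for every phenotype.")
  }
  if (any(idp_params$b0 <= 0) || any(idp_params$delta <= 0)) {
    abort("`b0` and `delta` must be positive for every phenotype.")
  }
  if (!is.list(contamination) ||
      !all(vapply(contamination, inherits, logical(1), "artefact_spec"))) {
    abort("`contamination` must be a list of artefact_spec objects.")
  }
  prev <- vapply(contamination, function(a) a$prevalence, numeric(1))
  if (length(prev) > 0 && sum(prev) >= 1) {
    abort("`contamination` prevalences must sum below 1.")
  }
  for (a in contamination) {
    bad <- setdiff(a$affected_idps, idp_names)
    if (length(bad) > 0L) {
      abort(sprintf("`contamination` names unknown phenotypes: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  check_number(rater_reliability, "rater_reliability", lower = 0, upper = 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = as.numeric(age_range),
                 idp_names = idp_names, idp_params = idp_params,
                 contamination = contamination,
                 rater_reliability = rater_reliability,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %d, ages [%g, %g], %d phenotypes, %d artefact class(es), seed %d\n",
    x$n_subjects, x$age_range[1], x$age_range[2], length(x$idp_names),
    length(x$contamination), x$seed))
  invisible(x)
}

# warped-scale age trend from control values at evenly spaced anchors
trend_fun <- function(control, age_range) {
  anchors <- seq(age_range[1], age_range[2], length.out = length(control))
  stats::splinefun(anchors, control, method = "natural")
}

#' Simulate a cohort table
#'
#' Draws ages uniformly over the age range; clean phenotype values
#' follow `y = warp_inverse(trend(age) + noise)` with Gaussian
#' warped-scale noise, so residuals are skewed / heavy-tailed on the
#' observed scale exactly as the normative model family assumes.
#' Contaminated subjects (assigned per [artefact_spec()] prevalence)
#' are displaced by `shift_sd` residual SDs on the deviation scale in
#' their affected phenotypes only (so the displacement is directly
#' comparable to a z threshold). Optionally appends simulated rater scores and the
#' 21-descriptor quantitative-QC table. Deterministic given the spec's
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param raters Append `rater1`/`rater2` columns (default TRUE).
#' @param qqc Append the 21 quantitative-QC descriptor columns
#'   (default TRUE).
#' @param qqc_effect_size Effect size passed to [simulate_qqc()].
#' @return A tibble with `subject_id`, `age`, `sex`, `true_category`,
#'   one column per phenotype, and optional rater / QC columns. The
#'   per-phenotype clean residual SDs used for contamination are
#'   attached as attribute `clean_resid_sd`.
#' @export
simulate_cohort <- function(spec, raters = TRUE, qqc = TRUE,
                            qqc_effect_size = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  run_seeded(spec$seed, {
    n <- spec$n_subjects
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)

    prev <- vapply(spec$contamination, function(a) a$prevalence, numeric(1))
    cats <- c("clean", vapply(spec$contamination, function(a) a$category,
                              character(1)))
    true_category <- sample(cats, n, replace = TRUE,
                            prob = c(1 - sum(prev), prev))

    idp_cols <- list()
    resid_sd <- numeric(0)
    for (i in seq_len(nrow(spec$idp_params))) {
      p <- spec$idp_params[i, ]
      w <- warp_params(epsilon = p$epsilon, delta = p$delta,
                       a0 = p$a0, b0 = p$b0)
      tr <- trend_fun(p$trend[[1]], spec$age_range)
      t_val <- tr(age) + rnorm(n, 0, p$noise_scale)
      for (a in spec$contamination) {
        if (p$idp %in% a$affected_idps) {
          hit <- true_category == a$category
          t_val[hit] <- t_val[hit] + a$shift_sd * p$noise_scale
        }
      }
      y <- warp_inverse(t_val, w)
      median_curve <- warp_inverse(tr(age), w)
      clean_mask <- true_category == "clean"
      rs <- if (any(clean_mask)) {
        sd(y[clean_mask] - median_curve[clean_mask])
      } else {
        sd(y - median_curve)
      }
      idp_cols[[p$idp]] <- y
      resid_sd[p$idp] <- rs
    }

    out <- tibble(subject_id = sprintf("S%05d", seq_len(n)),
                  age = age, sex = sex, true_category = true_category)
    out <- dplyr::bind_cols(out, as_tibble(idp_cols))

    if (raters) {
      truth <- true_severity(spec, true_category)
      rs2 <- simulate_rater_scores(truth, spec$rater_reliability)
      out <- dplyr::bind_cols(out, rs2)
    }
    if (qqc) {
      out <- dplyr::bind_cols(
        out, simulate_qqc(out, effect_size = qqc_effect_size))
    }
    attr(out, "clean_resid_sd") <- resid_sd
    attr(out, "seed") <- spec$seed
    out
  })
}

true_severity <- function(spec, true_category) {
  sev <- setNames(
    vapply(spec$contamination, function(a) a$severity_score, numeric(1)),
    vapply(spec$contamination, function(a) a$category, character(1)))
  ifelse(true_category == "clean", 1, sev[true_category])
}

#' Simulate two raters' visual QC scores
#'
#' Each rater independently reports the true severity with probability
#' `reliability`; otherwise they confuse it with an adjacent severity
#' (truth +/- 1 with equal probability), clipped to the 1--3 scale.
#' `reliability = 1` makes both raters equal the truth.
#'
#' @param truth Integer vector of true severities in `{1, 2, 3}`.
#' @param reliability Probability of reporting the truth, in `[0, 1]`.
#' @param seed Optional seed; `NULL` uses the current RNG stream (as
#'   when called inside [simulate_cohort()]).
#' @return A tibble with integer columns `rater1`, `rater2`.
#' @export
simulate_rater_scores <- function(truth, reliability, seed = NULL) {
  if (!all(truth %in% c(1, 2, 3))) {
    abort("`truth` severities must all be in {1, 2, 3}.")
  }
  check_number(reliability, "reliability", lower = 0, upper = 1)
  run_seeded(seed, {
    one_rater <- function() {
      keep <- runif(length(truth)) < reliability
      bump <- sample(c(-1L, 1L), length(truth), replace = TRUE)
      score <- ifelse(keep, truth, pmin(pmax(truth + bump, 1L), 3L))
      as.integer(score)
    }
    tibble(rater1 = one_rater(), rater2 = one_rater())
  })
}

# descriptor panel: plausible per-subject diffusion QC metrics
# (motion, outlier slices, SNR/CNR, registration discrepancies); 21 in
# total. `lower_is_worse` marks quality-signed metrics.
qqc_descriptor_defaults <- function() {
  tibble::tribble(
    ~name,                      ~mean,  ~sd,
    "avg_abs_motion",            0.45,  0.15,
    "avg_rel_motion",            0.25,  0.08,
    "translation_x",             0.20,  0.10,
    "translation_y",             0.25,  0.10,
    "translation_z",             0.30,  0.12,
    "rotation_x",                0.15,  0.05,
    "rotation_y",                0.12,  0.05,
    "rotation_z",                0.10,  0.04,
    "pct_outlier_slices",        0.60,  0.30,
    "pct_outlier_slices_b1000",  0.50,  0.25,
    "pct_outlier_slices_b2000",  0.80,  0.35,
    "snr_b0",                   22.0,   3.0,
    "cnr_b1000",                 1.10,  0.20,
    "cnr_b2000",                 0.65,  0.15,
    "eddy_ec_rms",               0.40,  0.15,
    "susceptibility_rms",        1.20,  0.40,
    "t1_dwi_discrepancy",        0.35,  0.08,
    "fa_template_discrepancy",   0.42,  0.09,
    "head_size_scaling",         1.05,  0.08,
    "mean_b0_intensity",      1500.0, 200.0,
    "tsnr_b0",                  18.0,   2.5)
}

# per-category descriptor loadings in SD units: acquisition artefacts
# raise motion / outlier slices and lower SNR/CNR; processing errors
# raise registration discrepancies; incidental findings mildly perturb
# anatomy-sensitive discrepancies.
qqc_loadings <- function() {
  list(
    acquisition = c(avg_abs_motion = 2.5, avg_rel_motion = 2.5,
                    translation_x = 1.5, translation_y = 1.5,
                    translation_z = 1.5, rotation_x = 1.5,
                    rotation_y = 1.5, rotation_z = 1.5,
                    pct_outlier_slices = 3, pct_outlier_slices_b1000 = 2.5,
                    pct_outlier_slices_b2000 = 2.5, snr_b0 = -2.5,
                    cnr_b1000 = -2, cnr_b2000 = -2, eddy_ec_rms = 2,
                    susceptibility_rms = 1.5, tsnr_b0 = -2),
    processing = c(t1_dwi_discrepancy = 3, fa_template_discrepancy = 3.5,
                   head_size_scaling = 1),
    incidental = c(t1_dwi_discrepancy = 1.5, fa_template_discrepancy = 1))
}

#' Simulate the 21-descriptor quantitative-QC table
#'
#' Draws each descriptor from its configured Gaussian baseline and
#' shifts contaminated subjects along category-specific loadings
#' (acquisition artefacts lower SNR/CNR and raise motion and outlier
#' slices; processing errors raise registration discrepancies), scaled
#' by `effect_size`. `effect_size = 0` makes clean and contaminated
#' distributions identical.
#'
#' @param cohort A cohort tibble with a `true_category` column (rows
#'   in subject order).
#' @param effect_size Multiplier on the category loadings (default 1).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A tibble with exactly 21 numeric descriptor columns, one row
#'   per cohort row.
#' @export
simulate_qqc <- function(cohort, effect_size = 1, seed = NULL) {
  check_number(effect_size, "effect_size")
  defs <- qqc_descriptor_defaults()
  loads <- qqc_loadings()
  categ <- cohort$true_category %||% rep("clean", nrow(cohort))
  n <- nrow(cohort)
  run_seeded(seed, {
    cols <- lapply(seq_len(nrow(defs)), function(i) {
      x <- rnorm(n, defs$mean[i], defs$sd[i])
      for (cat in names(loads)) {
        l <- loads[[cat]][defs$name[i]]
        if (!is.na(l)) {
          hit <- categ == cat
          x[hit] <- x[hit] + effect_size * l * defs$sd[i]
        }
      }
      x
    })
    names(cols) <- defs$name
    as_tibble(cols)
  })
}
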