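---
title: "Normative-modelling QC: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative-modelling QC: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normqc)
```

## The problem

Large imaging studies summarise each scan into imaging-derived
phenotypes (IDPs) — here, diffusion metrics (FA, MD, ICVF, ISOVF)
averaged over white-matter tracts. Corrupted acquisitions,
misregistrations and incidental anatomical findings leave traces in
these numbers even when nobody looks at the images. `normqc`
operationalises that idea: model each IDP's normal range across age in
a reference cohort, score every subject's deviation, and flag extreme
deviations for review. The package also implements the apparatus
needed to *evaluate* such a flagging rule against visual ratings and
quantitative quality descriptors.

## The normative model

For one phenotype, observations $y_n$ at ages $x_n$ are modelled as

$$\varphi(y_n) = \boldsymbol{\phi}(x_n)^\top \mathbf{w} + e_n,
  \qquad e_n \sim \mathcal N(0, \beta^{-1}),
  \qquad \mathbf{w} \sim \mathcal N(0, \alpha^{-1} I),$$

where $\boldsymbol\phi(x)$ is a cubic B-spline basis over age with
five evenly spaced knots spanning the training age range, boundary
knots clamped. The clamped basis is a partition of unity, so it spans
constants and no intercept column is needed; evaluation outside the
training ages clamps to the boundary (with a warning) rather than
extrapolating a cubic.

The warp is the sinh-arcsinh transform with an affine
pre-standardisation,

$$\varphi(y) = \sinh\!\big(\delta\,\mathrm{asinh}((y - a_0)/b_0) - \epsilon\big),$$

strictly increasing, with exact analytic inverse; $\epsilon$ generates
skew and $\delta$ tail weight, and $(\epsilon,\delta,a_0,b_0) =
(0,1,0,1)$ is the identity. Hyperparameters are chosen by minimising
the negative log marginal likelihood of the *observed* data — the
Gaussian evidence of the warped values plus the Jacobian term
$-\sum_n \log \varphi'(y_n)$ — with L-BFGS-B from three fixed-seed
starts ($\delta$, $b_0$, $\alpha$, $\beta$ on the log scale), so a fit
is deterministic given its seed. The weight posterior is the usual
conjugate pair $A = \alpha I + \beta\Phi^\top\Phi$,
$\mathbf m = \beta A^{-1}\Phi^\top \varphi(\mathbf y)$; constraining
the warp to the identity reduces the whole fit to closed-form Bayesian
linear regression, which the tests exploit as an oracle.

Per-subject deviations are
$$z_n = \frac{\varphi(y_n) - \boldsymbol\phi(x_n)^\top\mathbf m}
  {\sqrt{\beta^{-1} + \boldsymbol\phi(x_n)^\top A^{-1}\boldsymbol\phi(x_n)}},$$
computed on the warped scale — the only scale on which the residuals
are (approximately) Gaussian, so "standard deviations from the mean"
means what it says. Centile curves map warped-scale quantiles back
through the inverse warp; because the warp is monotone the median
curve is exactly the inverse-warped predictive mean and centiles never
cross. Explained variance is reported on the original scale
($1 - \mathrm{var}(y - \hat y)/\mathrm{var}(y)$ with $\hat y$ the
inverse-warped median), and skew/kurtosis are the Fisher and excess
moments of the z-scores.

### Identifiability of the warp, and the `standardize` modes

A finding that shaped the interface: with $(a_0, b_0)$ *learned
jointly* with $(\epsilon, \delta)$, the warp is practically
non-identified. The regression and noise precision absorb any affine
transformation of the warped scale, and over a finite data range a
different $(\epsilon, \delta, a_0, b_0)$ composed with an outer affine
can reproduce the original transform to numerical accuracy — a
likelihood ridge on which sampling noise, not the truth, decides the
optimum (we observed a generative $(\epsilon,\delta) = (0.5, 1.3)$
"recovered" as $(1.9, 2.7)$ with a *lower* NLL than the truth at
$n = 5000$). `fit_normative()` therefore exposes three conventions:

* `standardize = "fixed"` (default): $a_0, b_0$ pinned at the training
  mean and SD before shape optimisation — robust for phenotypes on
  arbitrary scales (MD $\sim 10^{-3}$, FA $\sim 0.5$);
* `standardize = "none"`: $a_0 = 0, b_0 = 1$, the exactly identified
  convention, appropriate when the data-generating warp is expressed
  in the same coordinates (as in the parameter-recovery tests);
* `standardize = "learn"`: the joint fit, kept as a diagnostic mode
  with the caveat above.

Calibration of z-scores and centiles is insensitive to the convention
(any member of the ridge Gaussianises equally well); only the
*interpretation* of $(\epsilon, \delta)$ as the generative values
requires the matched convention.

## The outlier rule

A subject–phenotype pair is flagged when $|z|$ strictly exceeds 7
(two-sided: artefacts can push a metric either way; both the direction
and the threshold are configurable). Under the null the expected flag
count is $nK \cdot 2\Phi(-7) \approx 0$ even at $nK = 120{,}000$
trials. Flag sets are nested in the threshold by construction.
Missing z-scores are refused, not dropped, to avoid silent subject
loss. Frequencies across phenotypes (and the "multi-IDP" subset
flagged in two or more) are the summaries carried into the comparison
battery, with artefact-category labels attached as bookkeeping after
review.

A caveat the tests make explicit: fitting the flexible warp on data
that *contain* a few percent of large artefacts lets $\epsilon,\delta$
absorb the artefact tail and collapse detection sensitivity — the
warp's job is to Gaussianise, and it cannot tell pathology from skew.
The controlled sensitivity experiment therefore fits the reference on
artefact-free subjects and scores the contaminated cohort against it;
the workflow of fitting on everything and *refitting after exclusion*
(`refit_compare()`, with its paired t-test of z before vs after) is
the practical mitigation when clean labels don't exist in advance.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not images: ages uniform on 45–85; per-phenotype values
$y = \varphi^{-1}(t)$ with $t = \mathrm{trend}(x) + \varepsilon$,
$\varepsilon \sim \mathcal N(0, \sigma)$ — i.e. the *fitted model
family itself* (a natural-spline trend specified by five control
values on the warped scale, plus warped Gaussian noise). This choice,
rather than an additive trend on the observed scale, is deliberate:
it gives parameter recovery, z calibration and centile coverage a
known truth to be checked against. Defaults: FA and ICVF decline with
age while MD and ISOVF rise; $\epsilon \in [0.25, 0.5]$ and
$\delta \in [0.85, 0.9]$ give the mild right skew and heavy tails
typical of tract-averaged diffusion metrics; the fornix gets 2.5× the
scale of other tracts to mimic its notoriously variable measurement.

Contamination is a per-subject multinomial over three rare classes:
acquisition artefacts (displace every phenotype, severity 3),
processing errors (preferentially MD and ISOVF, severity 2) and
incidental findings (one structure, severity 2), with default
prevalences 0.6% / 0.6% / 0.4%. The displacement `shift_sd` (default
10) acts on the *deviation scale* — the warped residual scale on which
z is measured — so its magnitude is directly comparable to the 7-SD
rule; an original-scale displacement of the same nominal size would be
Gaussianised down to ~6–7 deviations by the very warp that makes the
model work, making "10 SD" undetectable by construction.

Raters report the true severity with probability `reliability` and an
adjacent severity otherwise (clipped to 1–3); `reliability = 1` makes
both raters equal the truth, and independent raters arise only when
the truth is constant (an all-clean cohort), the regime used to test
near-zero ICC. The 21 quality descriptors (motion, translation,
rotation, outlier slices, SNR, per-shell CNR, registration
discrepancies, …) are Gaussian baselines with category-specific shifts
— acquisition artefacts lower SNR/CNR and raise motion and outlier
slices, processing errors raise registration discrepancies — scaled by
an `effect_size` whose zero value is an exact null.

What passing tests on this cohort do **not** show: robustness to
model-mismatched noise, site effects, non-uniform age sampling,
missing data, or artefacts that perturb covariance rather than
location. They show that the machinery is correct when its assumptions
hold, and the contamination experiments show how it degrades when the
training set is polluted.

## The comparison battery

* **ICC(3,k)** — two-way mixed, average-measures, consistency:
  $(\mathrm{MS}_{\text{subjects}} - \mathrm{MS}_{\text{error}}) /
  \mathrm{MS}_{\text{subjects}}$, computed from explicit mean squares
  (and cross-checked against an `aov()` decomposition in the tests);
  zero between-subject variance returns `NA` with a warning.
* **Balanced SVM** — visual scores binarised (1–2 acceptable, 3 not);
  the rare class kept whole and the acceptable class downsampled to
  match, 20 independent draws, each evaluated by stratified 5-fold
  cross-validation of a linear SVM (unit-variance scaling, cost 1 —
  defaults documented, not claimed as anyone else's), predictions
  pooled within a draw; single-class folds are redrawn with a logged
  message.
* **PR sweep** — area under the precision–recall curve by step-wise
  summation over all cut-points (ties grouped; no trapezoid, which is
  optimistic in PR space); baseline equals prevalence. A z threshold
  $t$ enters as the binary score $\mathbf 1\{\max_d |z_d| > t\}$, its
  curve the step through that operating point; the continuous
  $\max|z|$ ranking and SVM decision values are evaluated on the same
  footing.
* **Quantitative-QC outliers** — per descriptor, $|x - \bar x| >
  2\,\mathrm{SD}$ (two-sided by default, one-sided available for
  quality-signed metrics); zero-variance columns excluded with a
  warning.
* **Correlation matrix** — Pearson, over the six conventional
  measures (T1 discrepancy, FA-vs-DWI discrepancy, SNR, NM outlier
  frequency, QQC outlier frequency, visual score — rater 1 by
  convention, configurable).

## Numerical choices

Evidence optimisation uses numerical gradients with bounds
($\epsilon \in [-5, 5]$, $\delta \in [0.2, 5]$, log-precisions in
$[-25, 25]$), three restarts jittered from a moments-based start under
a fixed seed, and convergence reported in the model object
(non-convergence flags the model but keeps it usable). Cholesky
factorisations back all posterior algebra; $\log\cosh$ is computed
overflow-free; the identity warp short-circuits so identity parameters
are exact, not exact-to-rounding. Degenerate inputs error early with
the offending field named: constant responses, constant ages, fewer
than $M + 2$ observations, NaN z-scores, centile levels outside
$(0, 100)$, excluding $\ge 50\%$ in a refit.

## Problem sizes

The test suite and the acceptance script size their simulations for
sharp statistical checks at interactive runtimes: calibration at
10,000 train / 5,000 test, parameter recovery at 5,000, the null flag
count over a 5,000 × 24 z-table, the SVM harness at 400 subjects × 20
draws × 5 folds, and the end-to-end pipeline at 2,000 subjects run
twice for byte identity. The acceptance script uses a 9,000-subject
cohort with a 5,000-subject held-out test set, mirroring the design of
holding out a fixed random test sample.

## Known limitations

Age is the only covariate (sex is generated but unused, as a hook for
extension); no hierarchical or multi-site modelling; no automated
artefact-type classification — categories are review bookkeeping; the
warp family fixes one parameterisation of sinh-arcsinh and equivalence
with any other toolkit's internals is not claimed; EV/skew/kurtosis
are computed on held-out data by default, one of several defensible
conventions. And, as above: an ML-fitted likelihood warp is not a
robust estimator — heavily contaminated training data will be
partially "explained" by the warp, which is precisely why the package
ships the refit-after-exclusion comparison and the clean-reference
evaluation protocol.
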