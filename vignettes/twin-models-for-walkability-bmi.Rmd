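---
title: "Twin models for walkability and BMI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models for walkability and BMI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented in `twingem`,
the assumptions they rest on, the numerical choices made where the design
was genuinely open, and what the synthetic-data generator does and does not
emulate.

## The scientific setting

A continuous index of residential walkability (street connectivity, land-use
mix, green space and related built-environment features; higher is more
walkable) is observed for each member of a cohort of adult twin pairs
together with BMI (kg/m²), age, sex and four sociodemographic covariates
(work status, education, living status and a community deprivation z-score,
all coded so that employed = 1, bachelor-or-above = 1, living with
partner = 1, female = 1). Three questions structure the analysis:

1. Is walkability associated with BMI at the individual level, and does the
   association survive within-pair comparison (i.e., is it independent of
   genetic and shared early-environment confounding)?
2. How much of the variance in walkability itself is genetic — a
   gene–environment *correlation*, people partly selecting their
   environment?
3. Does walkability moderate the genetic and environmental contributions to
   BMI — a gene–environment *interaction*?

## Data model

`twin_cohort()` stores individual rows plus a derived pair table.
Twin order within a pair is canonicalized by sorting on `person_id`; every
likelihood in the package is invariant to this ordering (tested), and the
saturated model makes order effects explicitly testable instead of
implicitly baked into data layout. Individuals with a missing phenotype are
kept and filtered per analysis, never dropped globally, so a single cohort
object serves all stages; incomplete pairs enter the univariate likelihood
as singletons. CSV input is comma-separated UTF-8 with a header row and
empty string for missing; covariates may be median-imputed
(`impute_covariates_median()`, binary tie at 0.5 resolved to 1), phenotypes
never are.

Opposite-sex DZ pairs are modelled identically to same-sex DZ pairs beyond
the sex residualization; the package fits no sex-limitation models.

## Regression stage

`fit_ols_cluster()` computes ordinary least-squares point estimates;
inference uses the cluster-robust sandwich with clusters = twin pairs and
the CR1 small-sample factor G/(G−1)·(n−1)/(n−k) (delegated to
`sandwich::vcovCL(type = "HC1", cadjust = TRUE)`). This is the closed-form,
asymptotically equivalent counterpart of fitting the regression in an SEM
framework with a robust (MLR-type) estimator: the estimand and the
clustering correction are identical, so recovery is checked by simulation
rather than bit-level comparison with any particular SEM implementation.
Confidence intervals use the normal quantile 1.96 throughout, matching
large-sample SEM practice.

`fit_mz_pairwise()` implements the co-twin-control design on complete MZ
pairs: response and exposure are twin1 − twin2 differences, continuous
covariates are differenced, binary covariates enter as signed discordance
codes −1/0/+1 (a signed difference preserves directionality, which a
symmetric "discordant yes/no" coding would discard), sex enters at pair
level (MZ co-twins share sex), age is excluded (co-twins share age), and
classical OLS standard errors are used because pairs are independent units.
Everything genetic and everything shared within a pair cancels in the
differencing, which is the design's point; the package demonstrates this on
generated data where a purely pair-level confounder induces an
individual-level slope but a null within-pair slope.

## Univariate twin models

For one phenotype (residualized on age and sex beforehand via
`residualize_phenotype()`; the residual, not the raw value, enters the twin
model), the ACE model assumes phenotype = a·A + c·C + e·E with independent
standard-normal latents, A correlating 1.0 within MZ and 0.5 within DZ
pairs, C shared, E individual. ADE replaces C by dominance D (correlation
0.25 in DZ pairs); DE models without A are excluded as biologically
implausible. The starting model is chosen by the classical rule: ADE if and
only if the MZ intraclass correlation strictly exceeds twice the DZ one.

Estimation is full-information maximum likelihood: complete pairs
contribute bivariate-normal terms with the model-implied covariance,
singletons univariate terms, one mean shared across twins and zygosities.
Key numerical choices:

* **Parameterization.** Paths (a, c, e) are unbounded during optimization
  and squared into variance components, which imposes non-negativity
  implicitly; a path's sign is not identified and output is canonicalized
  non-negative. `e` is kept off an exact zero (a singular covariance);
  an estimate at that bound raises a warning flag.
* **Optimizer.** BFGS from moment-based starts (Falconer estimates from the
  sample twin correlations, clamped to [0.05, 0.9] and renormalized), plus
  jittered restarts using fixed multiplicative factors rather than random
  draws, so refits are bit-reproducible without touching the RNG. The
  restart log-likelihoods are retained on the fit object; agreement within
  1e-6 across restarts is a tested property.
* **Confidence intervals.** Standardized components get profile-likelihood
  intervals at the χ²(1) 95% cutoff (the asymmetry of variance-component
  intervals near 0 makes Wald intervals misleading); the profile
  re-maximizes over the mean, the total variance and the split of the
  remaining share, and endpoints are located by root-finding to 1e-6, with
  the component clamped to [0, 1] when the likelihood never crosses the
  cutoff.
* **Model comparison.** AIC = −2 logL + 2k with k = paths + mean; nested
  LRTs use χ² with df = parameter difference. A zero-df comparison of
  identical fits reports p = 1. Fits carry a data fingerprint so comparing
  fits from different observation sets is an error, not a silent mistake.

The intraclass correlation is the ML correlation of an exchangeable
bivariate normal (equal means and variances across twin order), which has
the closed form grand mean / average squared deviation / average
cross-product; its CI is a profile of the likelihood on the Fisher-z scale.
An ANOVA-type ICC would differ in small samples — the ML convention is
documented so small numeric differences from other software are expected,
not bugs.

The saturated model estimates a mean and variance per zygosity-by-order
cell plus one covariance per zygosity (10 parameters) and tests the
classical assumptions by imposing equality constraints (means/variances by
order/zygosity) with LRT df = number of imposed equalities. Under the
constraints that the data actually satisfy, constraint p-values are
uniform; this calibration is part of the test suite.

## Bivariate Cholesky moderation model

The moderator M (walkability) keeps its own ACE structure; BMI loads on
M's latent factors through shared paths (a_C, e_C, optionally c_C) and on
its own factors through unique paths (a_U, e_U). Each loading toward BMI is
moderated linearly by the twin's own observed moderator value m_i
(definition-variable convention): α_i = a_C + β_aC·m_i and so on. The
shared paths simultaneously encode gene–environment correlation, the betas
gene–environment interaction. With r the additive-genetic twin correlation
(1 MZ, 0.5 DZ), the pair-specific 4×4 expected covariance over
(M1, T1, M2, T2) is given in `?expected_cov_moderation`.

Design choices, each an open point in this model family:

* **Complete pairs only.** Definition-variable handling of a missing
  co-twin's moderator is not well defined; exclusion (with a count) is the
  conservative, testable choice. Singletons still contribute to the
  univariate stage.
* **Means.** μ_M and μ_T are constants; no regression of BMI's mean on M.
  The Cholesky shared paths already carry the phenotypic M–T covariance; a
  linear mean path on top (as in the fullest Purcell specification) would
  be an additional, partially redundant parameter. The betas-fixed model
  (`fix_betas = TRUE`) is the exact unmoderated bivariate Cholesky model
  and serves as the LRT null.
* **Moderator scale.** The residualized moderator enters as-is — no
  rescaling — so betas are per index unit and variance profiles span the
  observed residualized range.
* **Variant selection.** When the trait shows no shared-environment
  component in its own univariate fit, the shared-C path is dropped
  (`"no_shared_C"`); `compare_moderation_variants()` applies the
  AIC-difference-greater-than-2 rule and reports the LRT alongside.
* **Likelihood evaluation.** The per-pair 4×4 normal density is evaluated
  by conditioning (T1, T2) on (M1, M2): the M block is constant within
  zygosity, so the conditional mean and 2×2 conditional covariance have
  closed elementwise forms and the whole likelihood vectorizes over pairs.
  A plain per-pair `solve()`/`determinant()` implementation serves as the
  independent oracle in the tests (agreement to 1e-8).
* **Starts and restarts.** The moderated fit starts from an internal
  unmoderated prefit (moment-based starts) with betas released at zero,
  plus deterministic jittered restarts. The likelihood can have genuine
  local optima — one test documents a case where the zero-restart fit lands
  ~130 log-likelihood units below the optimum reached with restarts — so
  restarts are on by default and turning them off is a deliberate speed
  choice in tight simulation loops.

`variance_profile()` projects a fit onto a moderator grid:
var_A(m) = α(m)² + u(m)², var_E(m) = ε(m)² + w(m)², shares over their sum
(A and E only in the no-shared-C variant). A/E crossings are located by
sign-change bracketing on the grid followed by bisection to 1e-6 — the
curves are quadratics, but the numeric route is robust to any future
extension of the loading form. Two crossings with genetics dominant between
them and environment outside is the qualitative gene–environment
interaction signature the model is designed to exhibit.

## The synthetic-data generator

The generator is the package's evidence base: it produces cohorts from
exactly the latent-normal structure the likelihoods assume, which is what
makes parameter-recovery tests meaningful. Defaults mirror a combined
Finnish twin cohort of middle-aged adults — 477 MZ and 734 DZ complete
pairs; walkability mean 43.4, SD 12.0, with standardized variance
components 22%/22%/56%; BMI mean 26.5, SD ≈ 5.1; 60% female; age ≈ 43
(SD 5); covariate prevalences 89% employed, 62% bachelor-or-above, 72%
with partner — so recovery runs at the study's effective sample size rather
than an arbitrary one. Singletons arise by completely-at-random deletion
(FIML is valid under MCAR; no dropout mechanism is modelled). The
regression generator adds a latent household socioeconomic factor (70%
pair-shared) that drives the binary covariates through probit links and the
deprivation score, and optionally loads on walkability
(`covariate_walk_cor`), creating genuine confounding while keeping the
conditional walkability effect equal to `slope` by construction; the
moderation generator builds BMI from the twin's own realized moderator in
the loadings, matching how the fit conditions on the observed moderator.

What the generator does **not** emulate — and hence what passing recovery
tests do not establish about real data: non-Gaussian phenotypes (real BMI
is right-skewed), assortative mating, sibling interaction, informative
missingness, measurement error in self-reported BMI, sex-specific variance
components and any true mean effect of the moderator on BMI (exposed as
`slope` only in the regression generator, deliberately absent from the
moderation generator's default).

## Problem sizes in the test suite

The test suite favours a few deep parameterised checks per operation. The
replicate counts and pair counts are chosen as the smallest sizes at which
each property is statistically sharp: 100 replicates at 477 + 734 pairs for
the A/C/E recovery (Monte-Carlo SE of the mean ≈ 0.3 percentage points),
200 replicates for the intraclass correlations and for the null
calibration of the joint moderation-beta LRT (run at 120 + 180 pairs, where
the χ²(4) null holds as well as at full size), 100 replicates for each
regression recovery including 95% CI coverage, and single large cohorts
(10⁴ pairs per zygosity) for the Falconer-vs-FIML agreement checks. All
stochastic assertions use three Monte-Carlo standard errors of the
replicate mean.

## Known limitations

* Likelihood-based CIs are reported for standardized univariate components
  only; moderation betas currently get point estimates and LRTs, not
  intervals.
* The ICC and twin models assume multivariate normality of the
  (residualized) phenotype; heavy tails inflate the E component.
* The definition-variable likelihood treats the moderator as fixed per
  twin; with strong gene–environment correlation and strong moderation
  simultaneously this is an approximation, and the recovery tests quantify
  its bias only within the generator's parameter ranges.
* No liability-threshold (binary/ordinal) phenotypes, no extended
  pedigrees, no sex-limitation or scalar moderation of the moderator's own
  paths.
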