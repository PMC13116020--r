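#' @title Individual-level and co-twin-control regression
#' @description
#' Association analysis between walkability and BMI at the individual level,
#' with sandwich standard errors clustered on twin pairs (twins are not
#' independent observations), and the monozygotic co-twin-control design:
#' regressing within-MZ-pair BMI differences on within-pair walkability
#' differences, which cancels all genetic and shared early-environment
#' confounding by design.
#' @name phenotypic_regression
NULL

regfit <- function(coefficients, robust_se, r2, n_used, cluster_count,
                   model) {
  structure(list(
    coefficients = coefficients,
    robust_se = robust_se,
    ci95 = cbind(lower = coefficients - 1.96 * robust_se,
                 upper = coefficients + 1.96 * robust_se),
    r2 = r2, n_used = n_used, cluster_count = cluster_count, model = model
  ), class = "twingem_regfit")
}

#' @export
print.twingem_regfit <- function(x, ...) {
  cat("Regression fit (", x$model, "), n = ", x$n_used,
      ", clusters = ", x$cluster_count, ", R2 = ",
      formatC(x$r2, digits = 3, format = "f"), "\n", sep = "")
  tab <- data.frame(
    estimate = x$coefficients, se = x$robust_se,
    ci_lower = x$ci95[, "lower"], ci_upper = x$ci95[, "upper"]
  )
  print(round(tab, 4))
  invisible(x)
}

#' Ordinary least squares with pair-clustered sandwich standard errors
#'
#' Point estimates are plain OLS; standard errors are cluster-robust
#' sandwich estimates grouped by twin pair with the small-sample factor
#' `G/(G-1) * (n-1)/(n-k)` (G clusters, n observations, k parameters),
#' so they remain valid under arbitrary within-pair dependence.
#'
#' @param y numeric response.
#' @param X numeric design matrix including an intercept column.
#' @param clusters cluster (pair) labels, one per row of `X`.
#' @return A `twingem_regfit`: coefficients, robust SEs, normal-theory 95%
#'   CIs (`estimate +/- 1.96 * se`), `r2`, `n_used` and `cluster_count`.
#' @export
fit_ols_cluster <- function(y, X, clusters) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(clusters) == nrow(X))
  keep <- !is.na(y) & stats::complete.cases(X) & !is.na(clusters)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; clusters <- clusters[keep]
  n <- length(y); k <- ncol(X)
  if (qr(X)$rank < k) stop("singular design matrix")
  G <- length(unique(clusters))
  if (G < 2L) stop("need at least 2 clusters")
  if (G <= k) stop("fewer clusters (", G, ") than parameters (", k, ")")

  dat <- as.data.frame(X)
  dat$.y <- y
  fit <- stats::lm(.y ~ . + 0, data = dat)
  est <- stats::setNames(stats::coef(fit), colnames(X))
  resid <- stats::residuals(fit)
  # HC1-type cluster sandwich with the CR1 factor G/(G-1)*(n-1)/(n-k)
  V <- sandwich::vcovCL(fit, cluster = clusters, type = "HC1", cadjust = TRUE)
  se <- stats::setNames(sqrt(diag(V)), colnames(X))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  regfit(est, se, r2, n, G, "individual, cluster-robust")
}

#' Incremental R-squared of a nested model comparison
#'
#' @param full,reduced `twingem_regfit` objects fitted to the same
#'   observations, `reduced` nested in `full`.
#' @return `r2(full) - r2(reduced)` (non-negative; values within numerical
#'   noise of zero are clamped to 0).
#' @export
incremental_r2 <- function(full, reduced) {
  stopifnot(inherits(full, "twingem_regfit"),
            inherits(reduced, "twingem_regfit"))
  if (full$n_used != reduced$n_used) {
    stop("fits use different observation counts (", full$n_used, " vs ",
         reduced$n_used, ")")
  }
  d <- full$r2 - reduced$r2
  if (d < -1e-8) stop("reduced model fits better; models are not nested")
  max(d, 0)
}

# Design matrix for the individual-level model on a cohort.
individual_design <- function(cohort, adjust) {
  d <- cohort$individuals
  X <- cbind(
    intercept = 1,
    walkability = d$walkability,
    age = d$age,
    female = as.numeric(d$sex == "female")
  )
  if (adjust == "full") {
    X <- cbind(X,
               work_employed = d$work_employed,
               edu_high = d$edu_high,
               lives_with_partner = d$lives_with_partner,
               deprivation_z = d$deprivation_z)
  }
  X
}

#' Individual-level walkability-BMI regression on a cohort
#'
#' Convenience wrapper around [fit_ols_cluster()]: regresses BMI on
#' walkability with the minimal (age, sex) or full (plus work status,
#' education, living status, deprivation z-score) adjustment set, clustered
#' on twin pairs.
#'
#' @param cohort a [twin_cohort()] (covariates imputed beforehand for the
#'   full model; see [impute_covariates_median()]).
#' @param adjust `"minimal"` or `"full"`.
#' @return A `twingem_regfit`.
#' @export
fit_individual <- function(cohort, adjust = c("minimal", "full")) {
  stopifnot(inherits(cohort, "twin_cohort"))
  adjust <- match.arg(adjust)
  d <- cohort$individuals
  fit_ols_cluster(d$bmi, individual_design(cohort, adjust), d$pair_id)
}

#' Monozygotic co-twin-control (within-pair difference) regression
#'
#' For complete MZ pairs with both phenotypes observed, regresses the
#' within-pair BMI difference (twin 1 minus twin 2 in canonical order) on
#' the within-pair walkability difference. Continuous covariates enter as
#' within-pair differences; binary covariates as signed discordance codes
#' (-1, 0, +1, twin 1 minus twin 2); sex enters as the pair-level value
#' (MZ co-twins share sex); age is excluded (co-twins share age). Classical
#' OLS standard errors are used: pairs are independent units here.
#'
#' @param cohort a [twin_cohort()].
#' @param adjust `"minimal"` (difference predictor and pair sex only) or
#'   `"full"` (plus discordance/difference covariates).
#' @return A `twingem_regfit` with `cluster_count` equal to the number of
#'   pairs used.
#' @export
fit_mz_pairwise <- function(cohort, adjust = c("minimal", "full")) {
  stopifnot(inherits(cohort, "twin_cohort"))
  adjust <- match.arg(adjust)
  d <- cohort$individuals
  p <- cohort$pairs[cohort$pairs$zygosity == "MZ" & cohort$pairs$complete, ,
                    drop = FALSE]
  if (nrow(p) == 0L) stop("no complete MZ pairs in cohort")
  i1 <- match(p$id1, d$person_id)
  i2 <- match(p$id2, d$person_id)
  ok <- !is.na(d$bmi[i1]) & !is.na(d$bmi[i2]) &
    !is.na(d$walkability[i1]) & !is.na(d$walkability[i2])
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0L) stop("no MZ pairs with both phenotypes observed")

  dy <- d$bmi[i1] - d$bmi[i2]
  X <- cbind(
    intercept = 1,
    d_walkability = d$walkability[i1] - d$walkability[i2],
    female = as.numeric(d$sex[i1] == "female")
  )
  if (adjust == "full") {
    X <- cbind(X,
               d_work_employed = d$work_employed[i1] - d$work_employed[i2],
               d_edu_high = d$edu_high[i1] - d$edu_high[i2],
               d_lives_with_partner =
                 d$lives_with_partner[i1] - d$lives_with_partner[i2],
               d_deprivation_z = d$deprivation_z[i1] - d$deprivation_z[i2])
  }
  keep <- !is.na(dy) & stats::complete.cases(X)
  dy <- dy[keep]; X <- X[keep, , drop = FALSE]
  if (stats::sd(X[, "d_walkability"]) == 0) {
    stop("all within-pair walkability differences are zero; ",
         "the co-twin-control predictor has no variance")
  }
  # drop constant columns other than the intercept (e.g. all pairs concordant)
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  const["intercept"] <- FALSE
  X <- X[, !const, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")

  dat <- as.data.frame(X)
  dat$.y <- dy
  fit <- stats::lm(.y ~ . + 0, data = dat)
  sm <- summary(fit)
  est <- stats::setNames(stats::coef(fit), colnames(X))
  se <- stats::setNames(sm$coefficients[, "Std. Error"], colnames(X))
  out <- regfit(est, se, sm$r.squared, length(dy), length(dy),
                "MZ co-twin control")
  out
}
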